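#' Uniformly sampled signal stream
#'
#' Container for a single-channel amplitude series sampled uniformly at `fs`
#' Hz starting at `t0` seconds. The timestamp of (1-based) sample `i` is
#' `t0 + (i - 1) / fs`. Annotation files on disk use the equivalent 0-based
#' sample index, so timestamps and file indices agree.
#'
#' @param samples Numeric amplitude vector (no NA/Inf).
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return An object of class `signal_stream`.
#' @export
signal_stream <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("samples must be non-empty")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples contain NA or non-finite values")
  }
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0)) stop("fs must be > 0")
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream> %d samples @ %g Hz (%.2f s from t0 = %g s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @rdname signal_stream
#' @param x A `signal_stream`.
#' @export
stream_times <- function(x) x$t0 + (seq_along(x$samples) - 1) / x$fs

#' Read a delimited signal file
#'
#' Reads a one-column (amplitude) or two-column (time_s, amplitude) delimited
#' text file. For two-column input the sampling rate is inferred from the
#' median time step and checked for uniformity; for one-column input `fs`
#' must be supplied and `t0 = 0` is assumed. An optional header line is
#' skipped automatically.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (required for one-column files).
#' @return A [signal_stream()].
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty signal file: ", path)
  first_tokens <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first_tokens)))
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0) stop("empty signal file (header only): ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  ncol <- length(parts[[1]])
  if (!ncol %in% c(1, 2)) stop("expected 1 or 2 columns, got ", ncol)
  bad_width <- which(vapply(parts, length, 1L) != ncol)
  if (length(bad_width) > 0) {
    stop("malformed row at line ", bad_width[1] + has_header, " of ", path)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = ncol, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    stop("parse error at line ", bad + has_header, " of ", path,
         ": non-numeric value")
  }
  if (ncol == 1) {
    if (is.null(fs)) stop("fs is required for one-column signal files")
    return(signal_stream(mat[, 1], fs = fs, t0 = 0))
  }
  tt <- mat[, 1]
  if (nrow(mat) < 2) stop("two-column signal needs at least 2 rows")
  dt <- diff(tt)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * stats::median(dt)) {
    stop("time column is not uniformly increasing")
  }
  signal_stream(mat[, 2], fs = 1 / stats::median(dt), t0 = tt[1])
}

#' Write a signal stream as two-column CSV
#'
#' @param stream A [signal_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(stream, path) {
  stopifnot(inherits(stream, "signal_stream"))
  df <- data.frame(time_s = sprintf("%.9f", stream_times(stream)),
                   amplitude = sprintf("%.9g", stream$samples))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the filter has zero phase and fiducial timestamps
#' are not shifted. Length is preserved.
#'
#' @param stream A [signal_stream()].
#' @param low,high Cutoff frequencies in Hz; `0 < low < high < fs/2`.
#' @param order Filter order (default 4).
#' @return A filtered `signal_stream`.
#' @export
bandpass_filter <- function(stream, low = 0.5, high = 5, order = 4) {
  stopifnot(inherits(stream, "signal_stream"))
  nyq <- stream$fs / 2
  if (!(low > 0 && low < high)) stop("require 0 < low < high")
  if (high >= nyq) stop("high cutoff must be below the Nyquist frequency ", nyq)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filtered <- as.numeric(signal::filtfilt(bf, stream$samples))
  signal_stream(filtered, fs = stream$fs, t0 = stream$t0)
}

#' Scaled first derivative of a stream
#'
#' Forward difference with the last value repeated (so the series keeps the
#' stream's length and index alignment), then min--max scaled to \[0, 1\]. A
#' constant-slope batch (zero-range raw derivative) degenerates to all ones
#' with a warning, so downstream likelihoods stay defined.
#'
#' @param stream A [signal_stream()] of length >= 2.
#' @return Numeric vector in \[0, 1\], same length as the stream.
#' @export
first_derivative <- function(stream) {
  stopifnot(inherits(stream, "signal_stream"))
  x <- stream$samples
  if (length(x) < 2) stop("stream too short for a derivative")
  d <- diff(x)
  d <- c(d, d[length(d)])
  rng <- range(d)
  if (rng[1] == rng[2]) {
    warning("constant-slope batch: derivative scaling degenerate, returning 1s")
    return(rep(1, length(d)))
  }
  (d - rng[1]) / (rng[2] - rng[1])
}

fiducial_labels <- c("SYS", "MS", "EP", "NF")

#' Fiducial point table
#'
#' @param index 1-based sample indices.
#' @param timestamp Timestamps in seconds (`t0 + (index - 1) / fs`).
#' @param label Labels among `SYS` (systolic peak), `MS` (max slope),
#'   `EP` (cycle endpoint/onset), `NF` (non-fiducial).
#' @return A `data.frame` with columns `index`, `timestamp`, `label`.
#' @export
fiducial_points <- function(index = integer(), timestamp = numeric(),
                            label = character()) {
  if (!all(label %in% fiducial_labels)) {
    stop("labels must be among: ", paste(fiducial_labels, collapse = ", "))
  }
  data.frame(index = as.integer(index), timestamp = as.numeric(timestamp),
             label = as.character(label), stringsAsFactors = FALSE)
}

#' Write fiducial annotations
#'
#' Writes `timestamp_s,sample_index,label` rows; `sample_index` is 0-based on
#' disk so `timestamp_s = t0 + sample_index / fs`. Input must be sorted by
#' timestamp. Round-trips losslessly with [read_annotations()].
#'
#' @param points A fiducial-point `data.frame` (see [fiducial_points()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(points, path) {
  stopifnot(is.data.frame(points),
            all(c("index", "timestamp", "label") %in% names(points)))
  if (is.unsorted(points$timestamp)) stop("points must be sorted by timestamp")
  lines <- c("timestamp_s,sample_index,label",
             sprintf("%.6f,%d,%s", points$timestamp, points$index - 1L,
                     points$label))
  writeLines(lines, path)
  invisible(path)
}

#' Read fiducial annotations
#'
#' @param path Annotation CSV written by [write_annotations()].
#' @return A fiducial-point `data.frame` (1-based `index`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp_s", "sample_index", "label") %in% names(df))) {
    stop("annotation file must have columns timestamp_s,sample_index,label")
  }
  fiducial_points(index = df$sample_index + 1L, timestamp = df$timestamp_s,
                  label = df$label)
}

#' Annotated single-cycle template
#'
#' One cardiac cycle (onset to next onset) with its fiducial sample indices.
#' The ordering `onset_idx < ms_idx < sys_idx` is enforced: the onset precedes
#' the maximum-slope point, which precedes the systolic peak.
#'
#' @param samples Amplitude series of the cycle.
#' @param fs Sampling rate in Hz.
#' @param onset_idx,ms_idx,sys_idx 1-based fiducial indices into `samples`.
#' @param id Template identifier.
#' @param usage_count Times this template has won a region (never decreases).
#' @return An object of class `annotated_template`.
#' @export
annotated_template <- function(samples, fs, onset_idx, ms_idx, sys_idx,
                               id = "template", usage_count = 0L) {
  samples <- as.numeric(samples)
  if (length(samples) < 3) stop("template too short")
  idx <- c(onset_idx, ms_idx, sys_idx)
  if (any(idx < 1) || any(idx > length(samples))) {
    stop("fiducial indices out of template range")
  }
  if (!(onset_idx < ms_idx && ms_idx < sys_idx)) {
    stop("template fiducials must satisfy onset < max-slope < systolic peak")
  }
  structure(list(samples = samples, fs = fs,
                 onset_idx = as.integer(onset_idx),
                 ms_idx = as.integer(ms_idx),
                 sys_idx = as.integer(sys_idx),
                 id = as.character(id),
                 usage_count = as.integer(usage_count)),
            class = "annotated_template")
}

#' @export
print.annotated_template <- function(x, ...) {
  cat(sprintf(
    "<annotated_template '%s'> %d samples @ %g Hz; onset=%d MS=%d SYS=%d; used %d\n",
    x$id, length(x$samples), x$fs, x$onset_idx, x$ms_idx, x$sys_idx,
    x$usage_count))
  invisible(x)
}

#' Write / read a template (CSV amplitudes + JSON sidecar)
#'
#' The amplitude series goes to `<path>.csv` (one value per row) and the
#' metadata (`fs`, 0-based fiducial indices, `id`) to `<path>.json`.
#'
#' @param template An [annotated_template()].
#' @param path Base path without extension.
#' @return Base `path`, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "annotated_template"))
  writeLines(sprintf("%.9g", template$samples), paste0(path, ".csv"))
  meta <- list(fs = template$fs, onset_idx = template$onset_idx - 1L,
               ms_idx = template$ms_idx - 1L, sys_idx = template$sys_idx - 1L,
               id = template$id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(json)) {
    stop("template requires both ", csv, " and ", json)
  }
  samples <- as.numeric(readLines(csv, warn = FALSE))
  if (anyNA(samples)) stop("non-numeric value in template CSV")
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  annotated_template(samples, fs = meta$fs,
                     onset_idx = meta$onset_idx + 1L,
                     ms_idx = meta$ms_idx + 1L,
                     sys_idx = meta$sys_idx + 1L,
                     id = meta$id)
}

# Amplitude normalization used before DTW comparisons.
normalize_amplitude <- function(x, method = "minmax") {
  switch(method,
         none = x,
         minmax = {
           rng <- range(x)
           if (rng[1] == rng[2]) rep(0, length(x))
           else (x - rng[1]) / (rng[2] - rng[1])
         },
         zscore = {
           s <- stats::sd(x)
           if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
         },
         stop("unknown normalization: ", method))
}
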