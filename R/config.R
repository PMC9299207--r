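#' Pipeline configuration
#'
#' Builds the validated configuration list consumed by every stage of the
#' pipeline. Defaults follow the reference operating point for wearable PPG
#' at 300 Hz: a 4th-order zero-phase Butterworth band-pass at \[0.5, 5\] Hz,
#' endpoint search window fractions `alpha = 0.7` and `beta = 1.3` of the
#' average cycle length, and morphology-likelihood scale `gamma = 5000`.
#'
#' @param alpha Lower search-window bound as a fraction of the average cycle
#'   length `l_x`; must satisfy `0 < alpha < 1`.
#' @param beta Upper search-window bound as a fraction of `l_x`; must be > 1.
#' @param gamma Scale of the morphology likelihood `exp(-gamma * d)`.
#' @param batch_seconds Batch length in seconds over which the average cycle
#'   length is re-estimated and the derivative/amplitude are rescaled.
#' @param hr_band Plausible heart-rate band in Hz used to restrict the
#'   dominant-frequency search (default 0.5--3 Hz, i.e. 30--180 bpm).
#' @param bandpass Band-pass cutoff frequencies in Hz.
#' @param filter_order Butterworth filter order.
#' @param apply_filter Logical; band-pass the signal before analysis.
#' @param normalization Amplitude normalization applied to stream batches and
#'   templates before DTW: one of `"minmax"`, `"zscore"`, `"none"`.
#' @param reset_policy How a candidate that appears before `alpha * l_x`
#'   resets the cycle start: `"score_gated"` (adopt it only if its heuristic
#'   score beats the current start) or `"literal"` (always adopt it).
#' @param tolerance_ms Matching tolerance for evaluation, in milliseconds.
#' @param k Maximum number of templates in the dynamic ensemble.
#' @param region_seconds Stream length per dynamic-template update region.
#' @param reanalysis Logical; re-analyze a region with a freshly generated
#'   template and keep its cycles if it wins the selection.
#' @param dba_max_iter,dba_tol DTW barycenter averaging stopping rule.
#' @param ibi_bounds_ms Plausible interbeat-interval bounds in milliseconds.
#' @param spring_tau SPRING acceptance threshold; `NULL` calibrates it to the
#'   25th percentile of template-end distances over the first batch.
#' @param refine_fiducials Logical; snap each reported fiducial to the actual
#'   waveform landmark it names (local minimum for EP, local maximum for SYS,
#'   first-derivative maximum between them for MS) on a low-passed copy of
#'   the raw signal. Segmentation and the DTW mapping locate the landmark
#'   neighbourhood; refinement removes the timestamp bias the band-pass
#'   introduces.
#' @param refine_window_ms Half-width of the refinement search window (ms).
#' @param refine_lowpass_hz Low-pass cutoff of the localization signal (Hz);
#'   a pure low-pass does not move valleys or peaks, it only suppresses
#'   wideband noise.
#'
#' @return A list of class `ppg_config`.
#' @export
ppg_config <- function(alpha = 0.7,
                       beta = 1.3,
                       gamma = 5000,
                       batch_seconds = 60,
                       hr_band = c(0.5, 3.0),
                       bandpass = c(0.5, 5),
                       filter_order = 4,
                       apply_filter = TRUE,
                       normalization = c("minmax", "zscore", "none"),
                       reset_policy = c("score_gated", "literal"),
                       tolerance_ms = 30,
                       k = 3,
                       region_seconds = 30,
                       reanalysis = TRUE,
                       dba_max_iter = 30,
                       dba_tol = 1e-6,
                       ibi_bounds_ms = c(300, 1500),
                       spring_tau = NULL,
                       refine_fiducials = TRUE,
                       refine_window_ms = 60,
                       refine_lowpass_hz = 8) {
  normalization <- match.arg(normalization)
  reset_policy <- match.arg(reset_policy)
  cfg <- list(alpha = alpha, beta = beta, gamma = gamma,
              batch_seconds = batch_seconds, hr_band = hr_band,
              bandpass = bandpass, filter_order = filter_order,
              apply_filter = apply_filter, normalization = normalization,
              reset_policy = reset_policy, tolerance_ms = tolerance_ms,
              k = k, region_seconds = region_seconds, reanalysis = reanalysis,
              dba_max_iter = dba_max_iter, dba_tol = dba_tol,
              ibi_bounds_ms = ibi_bounds_ms, spring_tau = spring_tau,
              refine_fiducials = refine_fiducials,
              refine_window_ms = refine_window_ms,
              refine_lowpass_hz = refine_lowpass_hz)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  known <- names(formals(ppg_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  with(cfg, {
    if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
      stop("alpha must be in (0, 1)")
    }
    if (!(is.numeric(beta) && length(beta) == 1 && beta > 1)) {
      stop("beta must be > 1")
    }
    if (!(is.numeric(gamma) && gamma > 0)) stop("gamma must be > 0")
    if (!(batch_seconds > 0)) stop("batch_seconds must be > 0")
    if (!(length(hr_band) == 2 && hr_band[1] > 0 && hr_band[1] < hr_band[2])) {
      stop("hr_band must be increasing and positive")
    }
    if (!(length(bandpass) == 2 && bandpass[1] > 0 && bandpass[1] < bandpass[2])) {
      stop("bandpass must be increasing and positive")
    }
    if (!(k >= 1)) stop("k must be >= 1")
    if (!(region_seconds > 0)) stop("region_seconds must be > 0")
    if (!(length(ibi_bounds_ms) == 2 && ibi_bounds_ms[1] < ibi_bounds_ms[2])) {
      stop("ibi_bounds_ms must be increasing")
    }
    if (!(refine_window_ms > 0 && refine_lowpass_hz > 0)) {
      stop("refinement window and low-pass cutoff must be positive")
    }
  })
  structure(cfg, class = "ppg_config")
}

#' Read a configuration file
#'
#' Loads a YAML or JSON configuration file. Keys not understood by
#' [ppg_config()] are rejected; omitted keys take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `ppg_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(raw), names(formals(ppg_config)))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(ppg_config, raw)
}

#' @export
print.ppg_config <- function(x, ...) {
  cat("<ppg_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-14s %s\n", k,
                if (is.null(v)) "auto" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
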