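#' Boosted endpoint likelihood
#'
#' Fuses the domain-heuristic candidate likelihood with the DTW morphology
#' likelihood by their product, `P(e) = P(c|x) * P(d)`. Both factors are
#' scores in \[0, 1\] and are never renormalized.
#'
#' @param p_c Heuristic candidate likelihood(s) in \[0, 1\].
#' @param p_d Morphology likelihood(s) in \[0, 1\].
#' @return Product likelihood(s) in \[0, 1\].
#' @export
endpoint_likelihood <- function(p_c, p_d) {
  if (any(p_c < 0 | p_c > 1) || any(p_d < 0 | p_d > 1)) {
    stop("likelihoods must lie in [0, 1]")
  }
  p_c * p_d
}

# ---- batch plumbing ---------------------------------------------------------

# Batch index bounds: batches of config$batch_seconds; a trailing partial
# batch shorter than 2/hr_band[1] seconds is merged into the previous one.
batch_bounds <- function(n, fs, config) {
  blen <- max(3L, as.integer(round(config$batch_seconds * fs)))
  min_len <- 2 / config$hr_band[1] * fs
  starts <- seq(1L, n, by = blen)
  ends <- pmin(starts + blen - 1L, n)
  k <- length(starts)
  if (k > 1 && (ends[k] - starts[k] + 1) < min_len) {
    ends[k - 1] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }
  cbind(from = starts, to = ends)
}

# Per-batch min-max (or other) amplitude normalization over the whole stream.
batchwise_normalize <- function(x, fs, config) {
  b <- batch_bounds(length(x), fs, config)
  out <- numeric(length(x))
  for (r in seq_len(nrow(b))) {
    sl <- b[r, 1]:b[r, 2]
    out[sl] <- normalize_amplitude(x[sl], config$normalization)
  }
  out
}

# Precompute everything the endpoint search needs: per-batch cycle length,
# per-batch scaled derivative and normalized amplitude, and scored candidate
# endpoints over the full (filtered) stream.
prep_stream <- function(work, config) {
  x <- work$samples
  fs <- work$fs
  n <- length(x)
  b <- batch_bounds(n, fs, config)
  l_x <- numeric(nrow(b))
  deriv <- numeric(n)
  xnorm <- numeric(n)
  batch_of <- integer(n)
  for (r in seq_len(nrow(b))) {
    sl <- b[r, 1]:b[r, 2]
    batch <- signal_stream(x[sl], fs = fs, t0 = work$t0 + (b[r, 1] - 1) / fs)
    l_x[r] <- estimate_cycle_length(batch, band = config$hr_band)$l_x
    deriv[sl] <- first_derivative(batch)
    xnorm[sl] <- normalize_amplitude(x[sl], config$normalization)
    batch_of[sl] <- r
  }
  cand_idx <- detect_candidates(x)
  cand <- score_candidates(cand_idx, deriv)
  list(x = x, xnorm = xnorm, deriv = deriv, fs = fs, t0 = work$t0, n = n,
       bounds = b, l_x = l_x, batch_of = batch_of, cand = cand)
}

# ---- fiducial mapping -------------------------------------------------------

# Resolve one-to-many warping mappings: among all path pairs hitting template
# index j_target, take the stream index of minimum pointwise cost, earliest
# on ties.
map_one_fiducial <- function(path, costs, j_target) {
  hits <- which(path[, 2] == j_target)
  if (length(hits) == 0) stop("malformed path: template index ", j_target,
                              " not covered")
  best <- hits[which.min(costs[hits])]
  as.integer(path[best, 1])
}

#' Map template fiducials onto a detected cycle
#'
#' Transfers the template's maximum-slope and systolic-peak annotations onto
#' a cycle through the DTW warping path: each template fiducial index maps to
#' the aligned stream sample of minimum pointwise cost (earliest on ties).
#' The endpoint (EP) is by construction the cycle's first sample.
#'
#' @param cycle_samples Amplitude series of the detected cycle.
#' @param template An [annotated_template()].
#' @param path Optional result of [dtw_full()] aligning `cycle_samples` to
#'   `template$samples`; computed if omitted.
#' @return A `data.frame` with columns `label` (`EP`, `MS`, `SYS`) and
#'   `index` (1-based position within the cycle).
#' @export
map_fiducials <- function(cycle_samples, template, path = NULL) {
  stopifnot(inherits(template, "annotated_template"))
  if (is.null(path)) path <- dtw_full(cycle_samples, template$samples)
  pm <- path$path
  if (max(pm[, 2]) != length(template$samples)) {
    stop("malformed path: does not reach the template end")
  }
  data.frame(
    label = c("EP", "MS", "SYS"),
    index = c(1L,
              map_one_fiducial(pm, path$costs, template$ms_idx),
              map_one_fiducial(pm, path$costs, template$sys_idx)),
    stringsAsFactors = FALSE)
}

# Build a cycle record from normalized stream samples [s, e] (global indices).
build_cycle <- function(xnorm, s, e, template, ynorm, fs, t0) {
  path <- cpp_dtw_full(xnorm[s:e], ynorm)
  rel <- c(EP = 1L,
           MS = map_one_fiducial(path$path, path$costs, template$ms_idx),
           SYS = map_one_fiducial(path$path, path$costs, template$sys_idx))
  idx <- s + rel - 1L
  list(start = s, end = e,
       dtw_distance = path$distance, mean_cost = path$mean_cost,
       fiducials = fiducial_points(index = idx,
                                   timestamp = t0 + (idx - 1) / fs,
                                   label = names(rel)),
       template_id = template$id)
}

# ---- the boosted endpoint search -------------------------------------------

# Continuous search over precomputed stream state against one template.
# Starts at `start_at` (a candidate index; defaults to the first candidate)
# and keeps accepting cycles while the cycle start lies before `stop_at`.
run_search <- function(prep, template, config,
                       start_at = NULL, stop_at = Inf,
                       boost = TRUE) {
  cand <- prep$cand
  idx <- cand$index
  pc <- cand$p_c
  n <- prep$n
  ynorm <- normalize_amplitude(template$samples, config$normalization)
  cycles <- list()
  n_abandoned <- 0L

  if (length(idx) == 0) {
    warning("no candidate endpoints detected in stream")
    return(list(cycles = cycles, end_pos = NA_integer_,
                n_abandoned = n_abandoned))
  }
  start <- if (is.null(start_at)) idx[1] else as.integer(start_at)
  pc_at <- function(i) {
    p <- pc[match(i, idx)]
    if (is.na(p)) 0 else p
  }

  while (!is.na(start) && start < stop_at && start < n) {
    lx <- prep$l_x[prep$batch_of[start]]
    # (a) reset zone (start, start + alpha * l_x)
    repeat {
      la <- start + config$alpha * lx
      inner <- idx[idx > start & idx < la]
      if (length(inner) == 0) break
      if (config$reset_policy == "literal") {
        start <- inner[1]
      } else {
        better <- inner[pc[match(inner, idx)] > pc_at(start)]
        if (length(better) == 0) break
        start <- better[1]
      }
      lx <- prep$l_x[prep$batch_of[start]]
    }
    la <- start + config$alpha * lx
    lb <- start + config$beta * lx
    zone <- idx[idx >= la & idx <= min(lb, n)]
    if (length(zone) == 0) {
      # (c) abandon: restart at the first candidate after start + beta * l_x
      if (lb >= n) break
      nxt <- idx[idx > lb]
      if (length(nxt) == 0) break
      n_abandoned <- n_abandoned + 1L
      start <- nxt[1]
      next
    }
    # (b) accept the candidate maximizing P(e) = p_c * exp(-gamma * d);
    # computed in log space so gamma * d cannot underflow the comparison
    wend <- min(floor(lb), n)
    dser <- cpp_dtw_lastrow(prep$xnorm[start:wend], ynorm)
    dvals <- dser[zone - start + 1L]
    pcz <- if (boost) pc[match(zone, idx)] else rep(1, length(zone))
    log_pe <- log(pcz) - config$gamma * dvals
    pick <- order(-log_pe, dvals, zone)[1]
    e <- zone[pick]
    cycles[[length(cycles) + 1L]] <-
      build_cycle(prep$xnorm, start, e, template, ynorm, prep$fs, prep$t0)
    start <- e
  }
  list(cycles = cycles, end_pos = start, n_abandoned = n_abandoned)
}

# ---- fiducial refinement ------------------------------------------------------

# Localization signal: the raw stream with only wideband noise removed. A
# pure low-pass leaves valley/peak positions untouched (unlike the band-pass,
# whose high-pass leg tilts slow waveform segments), so landmarks snapped on
# it carry no filter-induced timestamp bias.
make_localization_signal <- function(stream, config) {
  if (!isTRUE(config$refine_fiducials)) return(NULL)
  fs <- stream$fs
  if (config$refine_lowpass_hz < fs / 2) {
    bf <- signal::butter(2, config$refine_lowpass_hz / (fs / 2), type = "low")
    as.numeric(signal::filtfilt(bf, stream$samples))
  } else {
    stream$samples
  }
}

# Snap each cycle's fiducials to the landmark they name on the localization
# signal: EP to the nearest local minimum, SYS to the nearest local maximum,
# MS to the first-derivative maximum between them. Cycle boundaries are not
# moved. Returns the cycles plus the refined final endpoint (the shared
# boundary onset closing the last cycle).
refine_cycles <- function(cycles, loc, fs, t0, config) {
  final_ep <- if (length(cycles) > 0) cycles[[length(cycles)]]$end else NA
  if (is.null(loc) || length(cycles) == 0) {
    return(list(cycles = cycles, final_ep = final_ep))
  }
  w <- max(1L, as.integer(round(config$refine_window_ms / 1000 * fs)))
  n <- length(loc)
  dloc <- diff(loc)
  # quadratic-vertex refinement: a local parabola fitted around a discrete
  # extremum averages the noise over the window instead of trusting a single
  # sample, which matters where the waveform is flat near the landmark
  vertex <- function(v, center, half, maximum) {
    a <- max(1L, center - half); b <- min(length(v), center + half)
    x <- (a:b) - center
    if (length(x) < 5) return(center)
    cf <- stats::lm.fit(cbind(1, x, x^2), v[a:b])$coefficients
    if (!is.finite(cf[3]) || cf[3] == 0) return(center)
    if (maximum != (cf[3] < 0)) return(center)
    vx <- -cf[2] / (2 * cf[3])
    if (abs(vx) > half) return(center)
    center + as.integer(round(vx))
  }
  half <- max(2L, as.integer(round(0.033 * fs)))
  snap <- function(i, fun) {
    a <- max(1L, i - w); b <- min(n, i + w)
    vertex(loc, a - 1L + fun(loc[a:b]), half,
           maximum = identical(fun, which.max))
  }
  for (k in seq_along(cycles)) {
    f <- cycles[[k]]$fiducials
    ep0 <- f$index[f$label == "EP"]
    ms0 <- f$index[f$label == "MS"]
    sys0 <- f$index[f$label == "SYS"]
    ep <- snap(ep0, which.min)
    sys <- snap(sys0, which.max)
    ms <- if (sys > ep + 1L) {
      vertex(dloc, ep - 1L + which.max(dloc[ep:(sys - 1L)]),
             max(2L, half %/% 2L), maximum = TRUE)
    } else {
      ms0
    }
    if (!(ep < ms && ms < sys)) { ep <- ep0; ms <- ms0; sys <- sys0 }
    idx <- c(ep, ms, sys)
    cycles[[k]]$fiducials <- fiducial_points(idx, t0 + (idx - 1) / fs,
                                             c("EP", "MS", "SYS"))
  }
  list(cycles = cycles, final_ep = snap(final_ep, which.min))
}

# ---- public segmentation ----------------------------------------------------

new_segmentation <- function(cycles, stream, config, method,
                             final_ep = NULL, ...) {
  fid <- collect_fiducials(cycles, stream$fs, stream$t0, final_ep)
  n_bad <- sum(vapply(cycles, function(cy) {
    i <- cy$fiducials$index
    !(i[1] <= i[2] && i[2] <= i[3] && i[3] <= cy$end)
  }, logical(1)))
  structure(list(cycles = cycles, fiducials = fid, method = method,
                 config = config, fs = stream$fs, t0 = stream$t0,
                 n_order_violations = n_bad, ...),
            class = "ppg_segmentation")
}

# One fiducial table for a run: per-cycle MS and SYS, plus the shared
# boundary onsets (every cycle's EP and the final accepted endpoint) as EP.
collect_fiducials <- function(cycles, fs, t0, final_ep = NULL) {
  if (length(cycles) == 0) return(fiducial_points())
  ep_idx <- vapply(cycles, function(cy) {
    cy$fiducials$index[cy$fiducials$label == "EP"]
  }, integer(1))
  if (is.null(final_ep)) final_ep <- cycles[[length(cycles)]]$end
  ep_idx <- unique(c(ep_idx, final_ep))
  other <- do.call(rbind, lapply(cycles, function(cy) {
    cy$fiducials[cy$fiducials$label != "EP", ]
  }))
  out <- rbind(fiducial_points(index = ep_idx,
                               timestamp = t0 + (ep_idx - 1) / fs,
                               label = rep("EP", length(ep_idx))),
               other)
  out <- out[!duplicated(out[c("index", "label")]), ]
  out[order(out$timestamp, out$label), , drop = FALSE]
}

#' Segment a PPG stream with a single template
#'
#' Runs the boosted endpoint search over the whole stream: per 60-s batch the
#' average cycle length `l_x` is re-estimated from the dominant frequency and
#' the derivative/amplitude are rescaled; candidate onsets (local minima) are
#' scored by following-upstroke steepness; and starting from the first
#' candidate, the endpoint of each cycle is the candidate in
#' `[start + alpha*l_x, start + beta*l_x]` maximizing the boosted likelihood
#' `P(e) = P(c|x) * exp(-gamma * d)`, where `d` is the running DTW distance
#' of the putative cycle against the template. A candidate arriving before
#' `alpha*l_x` resets the start per `config$reset_policy`; if the window is
#' empty the search abandons and restarts after `beta*l_x`. Accepted
#' endpoints become the next cycle's start, and template fiducials are mapped
#' onto each accepted cycle through the warping path. The incomplete trailing
#' cycle is discarded.
#'
#' @param stream A [signal_stream()].
#' @param template An [annotated_template()].
#' @param config A [ppg_config()].
#' @param boost Set `FALSE` to drop the heuristic factor (every candidate
#'   then carries `p_c = 1`); used for ablation.
#' @return A `ppg_segmentation` object: `cycles` (list of per-cycle records
#'   with boundaries, DTW distance, mean warping-path cost and fiducials) and
#'   `fiducials` (one table across the run).
#' @export
segment_stream <- function(stream, template, config = ppg_config(),
                           boost = TRUE) {
  stopifnot(inherits(stream, "signal_stream"),
            inherits(template, "annotated_template"))
  work <- if (config$apply_filter) {
    bandpass_filter(stream, config$bandpass[1], config$bandpass[2],
                    config$filter_order)
  } else {
    stream
  }
  prep <- prep_stream(work, config)
  res <- run_search(prep, template, config, boost = boost)
  ref <- refine_cycles(res$cycles, make_localization_signal(stream, config),
                       work$fs, work$t0, config)
  new_segmentation(ref$cycles, stream = work, config = config,
                   method = "boosted_st", final_ep = ref$final_ep,
                   n_abandoned = res$n_abandoned)
}

#' @export
print.ppg_segmentation <- function(x, ...) {
  cat(sprintf("<ppg_segmentation> method=%s, %d cycles, %d fiducials\n",
              x$method, length(x$cycles), nrow(x$fiducials)))
  if (x$n_order_violations > 0) {
    cat(sprintf("  note: %d cycle(s) with out-of-order fiducials\n",
                x$n_order_violations))
  }
  invisible(x)
}

#' Export a segmentation as files
#'
#' Writes the fiducial table as an annotation CSV and the cycle boundaries as
#' JSON (start/end timestamps, DTW distance, template id) with a provenance
#' block (package version, seed if known, config hash).
#'
#' @param seg A `ppg_segmentation`.
#' @param out_prefix Path prefix; writes `<prefix>_annotations.csv` and
#'   `<prefix>_cycles.json`.
#' @param seed Optional seed recorded in the provenance block.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_segmentation <- function(seg, out_prefix, seed = NULL) {
  stopifnot(inherits(seg, "ppg_segmentation"))
  ann <- paste0(out_prefix, "_annotations.csv")
  cyc <- paste0(out_prefix, "_cycles.json")
  write_annotations(seg$fiducials, ann)
  cycles <- lapply(seg$cycles, function(cy) {
    list(start_s = seg$t0 + (cy$start - 1) / seg$fs,
         end_s = seg$t0 + (cy$end - 1) / seg$fs,
         dtw_distance = cy$dtw_distance,
         mean_cost = cy$mean_cost,
         template_id = cy$template_id)
  })
  payload <- list(
    provenance = list(
      package = "ppgdtw",
      version = as.character(utils::packageVersion("ppgdtw")),
      seed = seed,
      config_hash = rlang::hash(unclass(seg$config)),
      method = seg$method),
    cycles = cycles)
  jsonlite::write_json(payload, cyc, auto_unbox = TRUE, digits = NA)
  invisible(c(annotations = ann, cycles = cyc))
}
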