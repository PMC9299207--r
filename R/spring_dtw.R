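#' Full dynamic time warping between two series
#'
#' Classic DTW with pointwise cost `|x_i - y_j|` (the Euclidean distance of
#' two scalars), steps down/right/diagonal and cumulative boundary
#' conditions. Backtracking prefers the diagonal step on ties, then the
#' vertical (stream) step, giving a deterministic shortest path.
#'
#' @param x,y Non-empty numeric series.
#' @return A list with `distance` (accumulated cost at the full alignment),
#'   `path` (two-column integer matrix of 1-based (stream, template) pairs),
#'   `costs` (pointwise cost along the path), and `mean_cost`
#'   (`distance / path length`, the average warping-path distance `|w|`).
#' @export
dtw_full <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("dtw_full: empty input")
  res <- cpp_dtw_full(x, y)
  colnames(res$path) <- c("i", "j")
  res
}

#' Streaming DTW distance against a full template
#'
#' `dtw_stream_init()` starts a fresh accumulation at the current putative
#' cycle start; each `dtw_stream_step()` consumes one stream sample and
#' returns the running distance `d_t` between the stream prefix (from that
#' start) and the complete template -- the last row of the full DP table.
#'
#' @param template Numeric template series (already normalized as desired).
#' @return For `dtw_stream_init`, a state list; for `dtw_stream_step`, a list
#'   with the updated `state` and the distance `d`.
#' @export
dtw_stream_init <- function(template) {
  template <- as.numeric(template)
  if (length(template) == 0) stop("empty template")
  list(template = template, col = numeric(0), t = 0L)
}

#' @rdname dtw_stream_init
#' @param state State from [dtw_stream_init()] or a previous step.
#' @param x_t Next stream sample.
#' @export
dtw_stream_step <- function(state, x_t) {
  col <- cpp_dtw_advance(state$col, x_t, state$template)
  state$col <- col
  state$t <- state$t + 1L
  list(state = state, d = col[length(col)])
}

#' Morphology likelihood of a DTW distance
#'
#' Maps an accumulated DTW distance `d >= 0` to `exp(-gamma * d)` in (0, 1]:
#' a strictly decreasing score that equals 1 only for a perfect match and
#' penalizes large distances exponentially.
#'
#' @param d Non-negative distance(s).
#' @param gamma Positive scale; the default matches the reference operating
#'   point under min--max amplitude normalization.
#' @return Likelihood value(s) in (0, 1].
#' @export
morphology_likelihood <- function(d, gamma = 5000) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (!(is.numeric(gamma) && gamma > 0)) stop("gamma must be > 0")
  exp(-gamma * d)
}

#' SPRING baseline segmentation
#'
#' The original subsequence-matching baseline: SPRING monitors the running
#' template-end distance over the stream with per-cell start pointers and
#' reports a match whenever that distance is a confirmed local minimum below
#' a threshold `tau`, with no overlapping better match pending. Matched
#' subsequences become cardiac cycles and their fiducials are mapped through
#' the full DTW path, exactly as in the boosted pipeline, so the two
#' approaches differ only in the endpoint decision rule.
#'
#' If `config$spring_tau` is `NULL`, `tau` is calibrated to the 25th
#' percentile of the template-end distances observed over the first batch.
#'
#' @param stream A [signal_stream()].
#' @param template An [annotated_template()].
#' @param config A [ppg_config()].
#' @return A `ppg_segmentation` object (see [segment_stream()]).
#' @export
spring_segment <- function(stream, template, config = ppg_config()) {
  stopifnot(inherits(stream, "signal_stream"),
            inherits(template, "annotated_template"))
  work <- if (config$apply_filter) {
    bandpass_filter(stream, config$bandpass[1], config$bandpass[2],
                    config$filter_order)
  } else {
    stream
  }
  fs <- work$fs
  xnorm <- batchwise_normalize(work$samples, fs, config)
  ynorm <- normalize_amplitude(template$samples, config$normalization)

  tau <- config$spring_tau
  if (is.null(tau)) {
    first <- seq_len(min(length(xnorm), round(config$batch_seconds * fs)))
    dm <- cpp_spring(xnorm[first], ynorm, tau = -1)$dm
    tau <- as.numeric(stats::quantile(dm, 0.25))
  }
  res <- cpp_spring(xnorm, ynorm, tau = tau)
  matches <- res$matches
  cycles <- list()
  if (nrow(matches) > 0) {
    for (k in seq_len(nrow(matches))) {
      s <- as.integer(matches[k, 1]); e <- as.integer(matches[k, 2])
      if (e - s + 1 < 3) next
      cycles[[length(cycles) + 1]] <-
        build_cycle(xnorm, s, e, template, ynorm, fs, work$t0)
    }
  }
  ref <- refine_cycles(cycles, make_localization_signal(stream, config),
                       fs, work$t0, config)
  new_segmentation(ref$cycles, stream = work, config = config,
                   method = "spring_baseline", final_ep = ref$final_ep,
                   tau = tau)
}
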