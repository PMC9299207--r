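#' Match predicted and ground-truth fiducial events
#'
#' Greedy nearest-in-time one-to-one matching within a tolerance window:
#' candidate (pred, truth) pairs are taken in order of increasing time gap,
#' each event matched at most once. Unmatched predictions are false
#' positives, unmatched truths false negatives.
#'
#' @param pred,truth Numeric timestamp vectors (seconds), or fiducial-point
#'   `data.frame`s restricted to a single label class.
#' @param tolerance_ms Matching tolerance in milliseconds.
#' @return A list of class `match_result`: `tp`, `fp`, `fn`, and
#'   `matched_pairs` (a `data.frame` with `pred_ts`, `truth_ts`).
#' @export
match_events <- function(pred, truth, tolerance_ms = 30) {
  if (is.data.frame(pred)) pred <- pred$timestamp
  if (is.data.frame(truth)) truth <- truth$timestamp
  pred <- sort(as.numeric(pred))
  truth <- sort(as.numeric(truth))
  tol <- tolerance_ms / 1000
  np <- length(pred); nt <- length(truth)
  pairs <- data.frame(pred_ts = numeric(0), truth_ts = numeric(0))
  if (np > 0 && nt > 0) {
    gaps <- abs(outer(pred, truth, "-"))
    cand <- which(gaps <= tol, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      g <- gaps[cand]
      ord <- order(g, cand[, 1], cand[, 2])
      used_p <- logical(np); used_t <- logical(nt)
      keep_p <- integer(0); keep_t <- integer(0)
      for (r in ord) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_p[i] && !used_t[j]) {
          used_p[i] <- TRUE; used_t[j] <- TRUE
          keep_p <- c(keep_p, i); keep_t <- c(keep_t, j)
        }
      }
      o <- order(pred[keep_p])
      pairs <- data.frame(pred_ts = pred[keep_p][o],
                          truth_ts = truth[keep_t][o])
    }
  }
  structure(list(tp = nrow(pairs), fp = np - nrow(pairs),
                 fn = nt - nrow(pairs), matched_pairs = pairs),
            class = "match_result")
}

#' Precision, recall and F1 of a match result
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. A metric with an
#' empty denominator is reported as `NA`; F1 is `NA` when either factor is
#' `NA` or when `precision + recall = 0`.
#'
#' @param m A `match_result` from [match_events()].
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(m) {
  precision <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
  recall <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Timestamp RMSE over matched pairs
#'
#' Root-mean-square timestamp error, in milliseconds, over true-positive
#' pairs only (RMSE compares time distances for positive predictions).
#'
#' @param m A `match_result` with at least one matched pair.
#' @return RMSE in milliseconds.
#' @export
timestamp_rmse <- function(m) {
  if (m$tp < 1) stop("no positive predictions: RMSE undefined")
  err_ms <- (m$matched_pairs$pred_ts - m$matched_pairs$truth_ts) * 1000
  sqrt(mean(err_ms^2))
}

#' Interbeat intervals from one class of fiducial points
#'
#' Successive differences of the fiducial timestamps, in milliseconds,
#' anchored at the later beat.
#'
#' @param points Fiducial-point `data.frame` (single label class) or numeric
#'   timestamps in seconds, sorted increasing.
#' @param source_label Label recorded on the series (`SYS`, `MS` or `EP`).
#' @return A list of class `ibi_series`: `values` (ms),
#'   `anchor_timestamps` (s), `source_label`.
#' @export
ibi_from_fiducials <- function(points, source_label = "SYS") {
  ts <- if (is.data.frame(points)) points$timestamp else as.numeric(points)
  if (length(ts) < 2) stop("need at least 2 fiducial points for IBIs")
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("fiducial timestamps must be strictly increasing")
  }
  structure(list(values = diff(ts) * 1000,
                 anchor_timestamps = ts[-1],
                 source_label = source_label),
            class = "ibi_series")
}

#' Physiological plausibility filter for IBIs
#'
#' Keeps intervals within `[lo, hi]` milliseconds (default 300--1500 ms).
#'
#' @param ibis An `ibi_series`.
#' @param lo,hi Bounds in milliseconds.
#' @return The filtered `ibi_series`.
#' @export
plausibility_filter <- function(ibis, lo = 300, hi = 1500) {
  stopifnot(inherits(ibis, "ibi_series"))
  keep <- ibis$values >= lo & ibis$values <= hi
  ibis$values <- ibis$values[keep]
  ibis$anchor_timestamps <- ibis$anchor_timestamps[keep]
  ibis
}

#' Agreement between predicted and reference IBI series
#'
#' Pairs each reference IBI with the predicted IBI whose anchor time is
#' closest, within a maximum anchor gap of 1 second, one-to-one and greedy
#' by time gap; reports mean absolute error (ms) and Pearson correlation
#' over the pairs.
#'
#' @param pred,truth `ibi_series` objects (already plausibility-filtered).
#' @param max_gap_s Maximum anchor time difference for pairing, in seconds.
#' @return A list: `mae_ms`, `pearson_r`, `n_pairs`.
#' @export
ibi_agreement <- function(pred, truth, max_gap_s = 1) {
  stopifnot(inherits(pred, "ibi_series"), inherits(truth, "ibi_series"))
  m <- match_events(pred$anchor_timestamps, truth$anchor_timestamps,
                    tolerance_ms = max_gap_s * 1000)
  if (m$tp == 0) {
    return(list(mae_ms = NA_real_, pearson_r = NA_real_, n_pairs = 0L))
  }
  pi <- match(m$matched_pairs$pred_ts, pred$anchor_timestamps)
  ti <- match(m$matched_pairs$truth_ts, truth$anchor_timestamps)
  pv <- pred$values[pi]
  tv <- truth$values[ti]
  r <- if (m$tp >= 3 && stats::sd(pv) > 0 && stats::sd(tv) > 0) {
    stats::cor(pv, tv)
  } else {
    NA_real_
  }
  list(mae_ms = mean(abs(pv - tv)), pearson_r = r, n_pairs = m$tp)
}

#' Per-class fiducial identification report
#'
#' Evaluates a predicted fiducial table against ground truth for each of the
#' `EP`, `MS`, `SYS` classes: precision, recall, F1 and timestamp RMSE at the
#' configured tolerance.
#'
#' @param pred,truth Fiducial-point `data.frame`s.
#' @param tolerance_ms Matching tolerance in milliseconds.
#' @return A `data.frame`, one row per class.
#' @export
evaluate_fiducials <- function(pred, truth, tolerance_ms = 30) {
  classes <- c("EP", "MS", "SYS")
  rows <- lapply(classes, function(cl) {
    m <- match_events(pred[pred$label == cl, ], truth[truth$label == cl, ],
                      tolerance_ms = tolerance_ms)
    met <- classification_metrics(m)
    data.frame(label = cl, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = met["precision"], recall = met["recall"],
               f1 = met["f1"],
               rmse_ms = if (m$tp > 0) timestamp_rmse(m) else NA_real_,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Per-source IBI estimation report
#'
#' Derives IBI series from each fiducial class of the prediction, applies
#' the plausibility filter, and scores MAE and Pearson correlation against
#' the reference beat-interval series.
#'
#' @param pred Predicted fiducial-point `data.frame`.
#' @param truth_beats Numeric vector of reference beat timestamps (s).
#' @param bounds_ms Plausibility bounds in milliseconds.
#' @param max_gap_s Maximum anchor gap for pairing, in seconds.
#' @return A `data.frame`, one row per source fiducial class.
#' @export
evaluate_ibi <- function(pred, truth_beats, bounds_ms = c(300, 1500),
                         max_gap_s = 1) {
  truth_ibi <- plausibility_filter(
    ibi_from_fiducials(sort(truth_beats), source_label = "EP"),
    bounds_ms[1], bounds_ms[2])
  rows <- lapply(c("EP", "MS", "SYS"), function(cl) {
    ts <- sort(unique(pred$timestamp[pred$label == cl]))
    if (length(ts) < 2) {
      return(data.frame(source = cl, mae_ms = NA_real_,
                        pearson_r = NA_real_, n = 0L))
    }
    ibis <- plausibility_filter(ibi_from_fiducials(ts, source_label = cl),
                                bounds_ms[1], bounds_ms[2])
    if (length(ibis$values) == 0) {
      return(data.frame(source = cl, mae_ms = NA_real_,
                        pearson_r = NA_real_, n = 0L))
    }
    ag <- ibi_agreement(ibis, truth_ibi, max_gap_s = max_gap_s)
    data.frame(source = cl, mae_ms = ag$mae_ms, pearson_r = ag$pearson_r,
               n = ag$n_pairs)
  })
  do.call(rbind, rows)
}
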