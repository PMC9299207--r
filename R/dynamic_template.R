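#' Template ensemble
#'
#' A bounded set of annotated single-cycle templates, initialized with the
#' prime (expert-annotated) template. The prime object is retained for
#' annotation transfer even if it is later evicted from the active set.
#'
#' @param prime The prime [annotated_template()].
#' @param k Maximum ensemble size.
#' @return An object of class `template_ensemble`.
#' @export
template_ensemble <- function(prime, k = 3) {
  stopifnot(inherits(prime, "annotated_template"), k >= 1)
  templates <- stats::setNames(list(prime), prime$id)
  structure(list(templates = templates, prime = prime, prime_id = prime$id,
                 k = as.integer(k), insertion = prime$id),
            class = "template_ensemble")
}

#' @export
print.template_ensemble <- function(x, ...) {
  cat(sprintf("<template_ensemble> %d/%d templates (prime: %s)\n",
              length(x$templates), x$k, x$prime_id))
  for (tpl in x$templates) {
    cat(sprintf("  %-12s used %d\n", tpl$id, tpl$usage_count))
  }
  invisible(x)
}

# DTW distance only (no backtracking).
dtw_distance <- function(x, y) {
  d <- cpp_dtw_lastrow(as.numeric(x), as.numeric(y))
  d[length(d)]
}

#' DTW barycenter averaging (DBA) consensus of detected cycles
#'
#' Cycles are linearly resampled to the median detected length, the average
#' is initialized from the medoid (minimum summed DTW distance to the rest),
#' and each iteration aligns every cycle to the current average and replaces
#' each average sample by the mean of all cycle samples warped onto it. The
#' DBA objective (summed DTW distance to the average) is non-increasing;
#' iteration stops when the mean absolute change of the average falls below
#' `tol` or after `max_iter` iterations.
#'
#' @param cycles Non-empty list of numeric amplitude series.
#' @param max_iter,tol Stopping rule.
#' @return A list with `consensus` (numeric series), `objective` (per-
#'   iteration summed DTW distance), and `iterations`.
#' @export
dba_consensus <- function(cycles, max_iter = 30, tol = 1e-6) {
  if (length(cycles) == 0) stop("dba_consensus: no cycles")
  cycles <- lapply(cycles, as.numeric)
  L <- as.integer(round(stats::median(vapply(cycles, length, 1L))))
  L <- max(L, 3L)
  rs <- lapply(cycles, function(v) {
    if (length(v) == L) v
    else stats::approx(seq_along(v), v, xout = seq(1, length(v), length.out = L))$y
  })
  m <- length(rs)
  if (m == 1) {
    return(list(consensus = rs[[1]], objective = 0, iterations = 0L))
  }
  dmat <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      dmat[i, j] <- dmat[j, i] <- dtw_distance(rs[[i]], rs[[j]])
    }
  }
  avg <- rs[[which.min(rowSums(dmat))]]
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    sums <- numeric(L)
    counts <- numeric(L)
    obj <- 0
    for (v in rs) {
      al <- cpp_dtw_full(v, avg)
      obj <- obj + al$distance
      j <- al$path[, 2]
      part <- rowsum(v[al$path[, 1]], j)
      sums[as.integer(rownames(part))] <- sums[as.integer(rownames(part))] +
        part[, 1]
      counts <- counts + tabulate(j, nbins = L)
    }
    objective <- c(objective, obj)
    new_avg <- sums / counts
    delta <- mean(abs(new_avg - avg))
    avg <- new_avg
    if (delta < tol) break
  }
  list(consensus = avg, objective = objective, iterations = length(objective))
}

#' Annotate a consensus cycle from the prime template
#'
#' Aligns the prime template to the consensus with DTW (both min--max
#' normalized for the alignment) and maps the prime's onset, maximum-slope
#' and systolic-peak indices through the warping path (minimum pointwise
#' cost, earliest on ties). A consensus whose mapped fiducials violate
#' onset < MS < SYS is rejected with an error.
#'
#' @param consensus Numeric consensus series.
#' @param prime The prime [annotated_template()].
#' @param id Identifier for the new template.
#' @return A new [annotated_template()] with `usage_count = 0`.
#' @export
annotate_consensus <- function(consensus, prime, id = NULL) {
  stopifnot(inherits(prime, "annotated_template"))
  consensus <- as.numeric(consensus)
  if (is.null(id)) {
    id <- paste0("dba-", substr(rlang::hash(consensus), 1, 8))
  }
  cn <- normalize_amplitude(consensus, "minmax")
  pn <- normalize_amplitude(prime$samples, "minmax")
  al <- cpp_dtw_full(cn, pn)
  onset <- map_one_fiducial(al$path, al$costs, prime$onset_idx)
  ms <- map_one_fiducial(al$path, al$costs, prime$ms_idx)
  sys <- map_one_fiducial(al$path, al$costs, prime$sys_idx)
  if (!(onset < ms && ms < sys)) {
    stop("consensus rejected: mapped fiducials violate onset < MS < SYS")
  }
  annotated_template(consensus, fs = prime$fs, onset_idx = onset,
                     ms_idx = ms, sys_idx = sys, id = id, usage_count = 0L)
}

#' Select the optimal template for a region
#'
#' The optimal template is the one with the lowest mean average-warping-path
#' cost `|w|` over the cycles it detected in the region. A template that
#' detected no cycles is treated as infinitely costly. Exact ties go to the
#' prime template, then to the earliest entry.
#'
#' @param region_results Named list (one entry per template id) of numeric
#'   vectors of per-cycle mean warping-path costs.
#' @param prime_id Identifier of the prime template.
#' @return The winning template id.
#' @export
select_optimal <- function(region_results, prime_id = NULL) {
  if (length(region_results) == 0) stop("select_optimal: empty results")
  means <- vapply(region_results, function(v) {
    v <- as.numeric(v)
    if (length(v) == 0 || all(is.na(v))) Inf else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(!is.finite(means))) return(names(means)[1])
  best <- min(means)
  tied <- names(means)[means == best]
  if (!is.null(prime_id) && prime_id %in% tied) return(prime_id)
  tied[1]
}

#' Update the template ensemble after a region
#'
#' If the ensemble is not full, a new consensus template (DBA over the
#' region's detected cycles, annotated from the prime) is added. If it is
#' full and the optimal template differs from the prime, the least
#' frequently used template -- counted as regions won, ties to the oldest
#' entry, never the just-selected optimum -- is evicted and the new consensus
#' added. Otherwise nothing changes. A region with no detected cycles
#' triggers no update.
#'
#' @param ensemble A [template_ensemble()].
#' @param region_cycles List of amplitude series of the cycles detected in
#'   the region by the optimal template.
#' @param region_results Per-template per-cycle mean path costs for the
#'   region (as in [select_optimal()]).
#' @param config A [ppg_config()] (DBA stopping rule, `reanalysis`).
#' @param new_id Optional id for the added template.
#' @return A list with `ensemble` (updated), `added_id` (or `NULL`), and
#'   `reanalysis` (`TRUE` when a template was added and reanalysis is
#'   enabled).
#' @export
update_ensemble <- function(ensemble, region_cycles, region_results,
                            config = ppg_config(), new_id = NULL) {
  stopifnot(inherits(ensemble, "template_ensemble"))
  if (length(region_cycles) == 0) {
    warning("region with no detected cycles: ensemble not updated")
    return(list(ensemble = ensemble, added_id = NULL, reanalysis = FALSE))
  }
  opt_id <- select_optimal(region_results, ensemble$prime_id)
  full <- length(ensemble$templates) >= ensemble$k
  if (full && opt_id == ensemble$prime_id) {
    return(list(ensemble = ensemble, added_id = NULL, reanalysis = FALSE))
  }
  consensus <- dba_consensus(region_cycles, max_iter = config$dba_max_iter,
                             tol = config$dba_tol)$consensus
  new_tpl <- tryCatch(
    annotate_consensus(consensus, ensemble$prime, id = new_id),
    error = function(e) {
      warning("consensus template rejected: ", conditionMessage(e))
      NULL
    })
  if (is.null(new_tpl)) {
    return(list(ensemble = ensemble, added_id = NULL, reanalysis = FALSE))
  }
  if (full) {
    pool <- setdiff(names(ensemble$templates), opt_id)
    usage <- vapply(ensemble$templates[pool], `[[`, 0L, "usage_count")
    least <- usage == min(usage)
    victim <- pool[least][order(match(pool[least], ensemble$insertion))][1]
    ensemble$templates[[victim]] <- NULL
  }
  ensemble$templates[[new_tpl$id]] <- new_tpl
  ensemble$insertion <- c(ensemble$insertion, new_tpl$id)
  list(ensemble = ensemble, added_id = new_tpl$id,
       reanalysis = isTRUE(config$reanalysis))
}

#' Segment a PPG stream with the dynamic template ensemble
#'
#' Processes the stream in regions of `config$region_seconds`. Every
#' template in the ensemble independently runs the boosted endpoint search
#' over the region; the template with the lowest mean warping-path cost wins
#' the region, its cycles are reported and its usage count incremented, and
#' the ensemble is updated per [update_ensemble()]. When a new template is
#' added and `config$reanalysis` is enabled, the region is re-analyzed with
#' it and the final selection includes the newcomer. With `k = 1` the run is
#' identical to [segment_stream()].
#'
#' @inheritParams segment_stream
#' @param prime The prime [annotated_template()].
#' @return A `ppg_segmentation` with the final `ensemble` attached.
#' @export
segment_stream_dynamic <- function(stream, prime, config = ppg_config()) {
  stopifnot(inherits(stream, "signal_stream"),
            inherits(prime, "annotated_template"))
  work <- if (config$apply_filter) {
    bandpass_filter(stream, config$bandpass[1], config$bandpass[2],
                    config$filter_order)
  } else {
    stream
  }
  prep <- prep_stream(work, config)
  ens <- template_ensemble(prime, k = config$k)
  idx <- prep$cand$index
  if (length(idx) == 0) {
    warning("no candidate endpoints detected in stream")
    return(new_segmentation(list(), stream = work, config = config,
                            method = "boosted_dt", ensemble = ens))
  }
  region_len <- max(3L, as.integer(round(config$region_seconds * prep$fs)))
  pos <- idx[1]
  all_cycles <- list()
  region_no <- 0L

  while (!is.na(pos) && pos < prep$n) {
    region_no <- region_no + 1L
    stop_at <- (floor((pos - 1) / region_len) + 1) * region_len + 1
    runs <- lapply(ens$templates, function(tpl) {
      run_search(prep, tpl, config, start_at = pos, stop_at = stop_at)
    })
    results <- lapply(runs, function(r) {
      vapply(r$cycles, `[[`, numeric(1), "mean_cost")
    })
    opt_id <- select_optimal(results, ens$prime_id)
    opt_cycles <- runs[[opt_id]]$cycles

    upd <- update_ensemble(
      ens, lapply(opt_cycles, function(cy) prep$xnorm[cy$start:cy$end]),
      results, config, new_id = sprintf("dba-r%03d", region_no))
    ens <- upd$ensemble
    final_id <- opt_id
    final_run <- runs[[opt_id]]
    if (!is.null(upd$added_id) && upd$reanalysis) {
      rerun <- run_search(prep, ens$templates[[upd$added_id]], config,
                          start_at = pos, stop_at = stop_at)
      results[[upd$added_id]] <- vapply(rerun$cycles, `[[`, numeric(1),
                                        "mean_cost")
      final_id <- select_optimal(results, ens$prime_id)
      if (final_id == upd$added_id) final_run <- rerun
    }
    if (final_id %in% names(ens$templates)) {
      ens$templates[[final_id]]$usage_count <-
        ens$templates[[final_id]]$usage_count + 1L
    }
    all_cycles <- c(all_cycles, final_run$cycles)

    new_pos <- final_run$end_pos
    if (is.na(new_pos) || new_pos <= pos) {
      nxt <- idx[idx >= stop_at]
      if (length(nxt) == 0) break
      new_pos <- nxt[1]
    }
    if (new_pos <= pos) break
    pos <- new_pos
  }
  ref <- refine_cycles(all_cycles, make_localization_signal(stream, config),
                       work$fs, work$t0, config)
  new_segmentation(ref$cycles, stream = work, config = config,
                   method = "boosted_dt", final_ep = ref$final_ep,
                   ensemble = ens)
}
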