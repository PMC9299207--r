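# Shared small fixtures: a clean 60-bpm recording and its template are used
# by several files; built once per test run.
quiet_spec <- function(duration_s = 20, hr_bpm = 60, seed = 11, ...) {
  simulation_spec(duration_s = duration_s, fs = 300, hr_bpm = hr_bpm,
                  am_depth = 0, bw_depth = 0, fm_depth = 0, noise_sd = 0,
                  seed = seed, ...)
}

clean_config <- function(...) {
  ppg_config(apply_filter = FALSE, refine_fiducials = FALSE, ...)
}

max_fiducial_err <- function(seg, truth, label) {
  p <- seg$fiducials$index[seg$fiducials$label == label]
  tr <- truth$index[truth$label == label]
  if (length(p) == 0) return(Inf)
  max(vapply(p, function(i) min(abs(tr - i)), numeric(1)))
}

pooled_f1 <- function(tab, label) {
  t2 <- tab[tab$label == label, ]
  2 * sum(t2$tp) / (2 * sum(t2$tp) + sum(t2$fp) + sum(t2$fn))
}

# Fig.-8-style stream: a compressed full-amplitude copy of one cycle (a
# meta-subsequence, like an ectopic beat) followed by a compensatory pause,
# spliced into an otherwise regular recording. Returns the stream, the
# template, and the premature/true endpoint indices.
meta_subsequence_stream <- function() {
  spec <- quiet_spec(12, seed = 3)
  sim <- simulate_ppg(spec)
  tpl <- make_prime_template(spec)
  ep <- sim$truth$index[sim$truth$label == "EP"]
  cyc <- sim$clean[ep[2]:(ep[3] - 1)]
  mini <- stats::approx(seq_along(cyc), cyc, n = 180)$y
  filler <- seq(mini[180], cyc[1], length.out = 121)[-1]
  x <- c(sim$clean[1:(ep[4] - 1)], mini, filler,
         sim$clean[(ep[4] + 300):length(sim$clean)])
  list(stream = signal_stream(x, 300), template = tpl,
       premature_end = ep[4] - 1 + 180, true_end = ep[4] - 1 + 300)
}
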