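test_that("endpoint likelihood is the product with its algebraic identities", {
  expect_equal(endpoint_likelihood(0.8, 0.5), 0.4)
  expect_equal(endpoint_likelihood(1.0, 0.37), 0.37)
  expect_equal(endpoint_likelihood(0.37, 1.0), 0.37)
  expect_equal(endpoint_likelihood(0, 0.99), 0)
  expect_error(endpoint_likelihood(1.2, 0.5), "\\[0, 1\\]")
  expect_error(endpoint_likelihood(0.5, -0.1), "\\[0, 1\\]")
})

test_that("map_fiducials is exact on identity and near-exact on 2x stretch", {
  spec <- quiet_spec(10)
  tpl <- make_prime_template(spec)
  ident <- map_fiducials(tpl$samples, tpl)
  expect_equal(ident$index, c(1L, tpl$ms_idx, tpl$sys_idx))

  stretched <- rep(tpl$samples, each = 2)
  m <- map_fiducials(stretched, tpl)
  expect_lte(abs(m$index[m$label == "MS"] - (2 * tpl$ms_idx - 1)), 1)
  expect_lte(abs(m$index[m$label == "SYS"] - (2 * tpl$sys_idx - 1)), 1)
})

test_that("one-to-many warp mappings resolve to earliest minimum cost", {
  y <- c(0, 0.5, 1, 0.5, 0)
  tpl <- annotated_template(y, 300, onset_idx = 1, ms_idx = 2, sys_idx = 3)
  x <- c(0, 0.5, 1, 1, 1, 0.5, 0)  # peak plateau of three equal-cost samples
  m <- map_fiducials(x, tpl)
  expect_equal(m$index[m$label == "SYS"], 3L)  # earliest of {3,4,5}
  bad <- dtw_full(x, y)
  bad$path <- bad$path[bad$path[, 2] < 5, , drop = FALSE]
  expect_error(map_fiducials(x, tpl, bad), "malformed path")
})

test_that("noiseless recovery: boundary-sharing cycles matching ground truth", {
  spec <- quiet_spec(20)
  sim <- simulate_ppg(spec)
  tpl <- make_prime_template(spec)
  seg <- segment_stream(sim$stream, tpl, clean_config())
  n_beats <- length(sim$beat_times)
  expect_gte(length(seg$cycles), n_beats - 2)
  starts <- vapply(seg$cycles, `[[`, numeric(1), "start")
  ends <- vapply(seg$cycles, `[[`, numeric(1), "end")
  expect_equal(starts[-1], ends[-length(ends)])  # shared boundaries
  cand <- detect_candidates(sim$stream$samples)
  expect_true(all(ends %in% cand))  # accepted endpoints are candidates
  for (lab in c("EP", "MS", "SYS")) {
    expect_lte(max_fiducial_err(seg, sim$truth, lab), 1)
  }
})

test_that("dicrotic-notch minima are never accepted as endpoints", {
  spec <- quiet_spec(20, morphology_schedule = list(
    list(time_s = 0, model = ppg_presets()$prominent_notch)))
  sim <- simulate_ppg(spec)
  tpl <- make_prime_template(spec)
  seg <- segment_stream(sim$stream, tpl, clean_config())
  ends <- vapply(seg$cycles, `[[`, numeric(1), "end")
  tr_ep <- sim$truth$index[sim$truth$label == "EP"]
  expect_true(all(vapply(ends, function(e) min(abs(tr_ep - e)) <= 1,
                         logical(1))))
})

test_that("a candidate-free gap causes one abandoned search, then recovery", {
  spec <- quiet_spec(16)
  sim <- simulate_ppg(spec)
  tpl <- make_prime_template(spec)
  x <- sim$stream$samples
  gap <- 2101:2700  # 2 s monotone ramp: no local minima inside
  x[gap] <- seq(x[2100], x[2701], length.out = length(gap) + 2)[2:601]
  seg <- segment_stream(signal_stream(x, 300), tpl, clean_config())
  expect_gte(seg$n_abandoned, 1)
  ends <- vapply(seg$cycles, `[[`, numeric(1), "end")
  expect_true(any(ends > 2700))  # search resumed after the gap
})

test_that("score-gated resets segment notched beats; the literal rule degenerates", {
  spec <- quiet_spec(20, morphology_schedule = list(
    list(time_s = 0, model = ppg_presets()$prominent_notch)))
  sim <- simulate_ppg(spec)
  tpl <- make_prime_template(spec)
  gated <- segment_stream(sim$stream, tpl,
                          clean_config(reset_policy = "score_gated"))
  expect_gte(length(gated$cycles), length(sim$beat_times) - 3)
  expect_lte(max_fiducial_err(gated, sim$truth, "EP"), 1)
  # the literal rule hands the start to every dicrotic-notch minimum, so it
  # keeps walking forward and closes far fewer cycles on notched morphology
  literal <- segment_stream(sim$stream, tpl,
                            clean_config(reset_policy = "literal"))
  expect_lte(length(literal$cycles), length(gated$cycles))
})

test_that("removing the boost never improves endpoint F1", {
  specs <- standard_suite_specs(3, 60, seed = 2)
  for (spec in specs) {
    sim <- simulate_ppg(spec)
    tpl <- make_prime_template(spec)
    cfg <- ppg_config()
    f1_boost <- evaluate_fiducials(
      segment_stream(sim$stream, tpl, cfg)$fiducials, sim$truth)$f1[1]
    f1_plain <- evaluate_fiducials(
      segment_stream(sim$stream, tpl, cfg, boost = FALSE)$fiducials,
      sim$truth)$f1[1]
    expect_lte(f1_plain, f1_boost + 1e-9)
  }
})

test_that("segmentation output files round-trip with provenance", {
  spec <- quiet_spec(12)
  sim <- simulate_ppg(spec)
  seg <- segment_stream(sim$stream, make_prime_template(spec), clean_config())
  out <- file.path(withr::local_tempdir(), "run")
  paths <- write_segmentation(seg, out, seed = 99)
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(seg$fiducials))
  payload <- jsonlite::read_json(paths[["cycles"]], simplifyVector = TRUE)
  expect_equal(length(payload$cycles$start_s), length(seg$cycles))
  expect_equal(payload$provenance$seed, 99)
  expect_true(nzchar(payload$provenance$config_hash))
})
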