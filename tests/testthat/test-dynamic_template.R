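test_that("DBA fixes identical cycles and single cycles", {
  cyc <- sin(seq(0, 2 * pi, length.out = 80)) + 1
  r1 <- dba_consensus(list(cyc))
  expect_equal(r1$consensus, cyc)
  rm_ <- dba_consensus(rep(list(cyc), 5))
  expect_equal(rm_$consensus, cyc, tolerance = 1e-9)
  expect_error(dba_consensus(list()), "no cycles")
})

test_that("DBA objective is non-increasing and the consensus is central", {
  set.seed(3)
  base <- sin(seq(0, 2 * pi, length.out = 90)) + 1
  shifted <- c(base[6:90], base[1:5])
  r <- dba_consensus(list(base, shifted))
  expect_true(all(diff(r$objective) <= 1e-9))
  d12 <- dtw_full(base, shifted)$distance
  expect_lte(dtw_full(r$consensus, base)$distance, d12 + 1e-9)
  expect_lte(dtw_full(r$consensus, shifted)$distance, d12 + 1e-9)
})

test_that("annotation transfer preserves, stretches, and rejects", {
  spec <- quiet_spec(10)
  prime <- make_prime_template(spec)
  same <- annotate_consensus(prime$samples, prime, id = "c0")
  expect_equal(same$ms_idx, prime$ms_idx)
  expect_equal(same$sys_idx, prime$sys_idx)
  expect_equal(same$usage_count, 0L)

  doubled <- annotate_consensus(rep(prime$samples, each = 2), prime, id = "c2")
  expect_lte(abs(doubled$ms_idx - (2 * prime$ms_idx - 1)), 1)
  expect_lte(abs(doubled$sys_idx - (2 * prime$sys_idx - 1)), 1)

  expect_error(annotate_consensus(rep(1, 50), prime), "rejected|onset")
})

test_that("optimal-template selection minimizes mean cost with prime ties", {
  expect_equal(select_optimal(list(A = c(0.1, 0.1)), "A"), "A")
  expect_equal(select_optimal(list(A = 0.10, B = 0.07), "A"), "B")
  expect_equal(select_optimal(list(A = 0.07, B = 0.07), "A"), "A")  # tie
  expect_equal(select_optimal(list(B = 0.07, C = 0.07), "A"), "B")
  expect_error(select_optimal(list()), "empty")
})

test_that("ensemble update grows, holds, and evicts by usage", {
  spec <- quiet_spec(10)
  prime <- make_prime_template(spec)
  sim <- simulate_ppg(spec)
  ep <- sim$truth$index[sim$truth$label == "EP"]
  cycles <- lapply(1:4, function(k) sim$clean[ep[k]:ep[k + 1]])
  cfg <- ppg_config(k = 2)

  ens <- template_ensemble(prime, k = 2)
  up1 <- update_ensemble(ens, cycles, list(prime = 0.1), cfg, new_id = "n1")
  expect_equal(length(up1$ensemble$templates), 2)
  expect_equal(up1$added_id, "n1")
  expect_true(up1$reanalysis)

  # full, prime optimal: no change
  up2 <- update_ensemble(up1$ensemble, cycles,
                         list(prime = 0.05, n1 = 0.2), cfg, new_id = "n2")
  expect_null(up2$added_id)
  expect_equal(names(up2$ensemble$templates), c("prime", "n1"))

  # full, other optimal: least-used (never the optimum) is evicted
  ens3 <- up1$ensemble
  ens3$templates$prime$usage_count <- 5L
  ens3$templates$n1$usage_count <- 1L
  up3 <- update_ensemble(ens3, cycles, list(prime = 0.3, n1 = 0.1), cfg,
                         new_id = "n3")
  expect_equal(up3$added_id, "n3")
  expect_equal(sort(names(up3$ensemble$templates)), c("n1", "n3"))

  expect_warning(up4 <- update_ensemble(ens, list(), list(prime = 0.1), cfg),
                 "no detected cycles")
  expect_null(up4$added_id)
})

test_that("with k = 1 the dynamic run is identical to the single-template run", {
  spec <- quiet_spec(25, seed = 4)
  spec$noise_sd <- 0.02
  sim <- simulate_ppg(spec)
  tpl <- make_prime_template(spec)
  st <- segment_stream(sim$stream, tpl, ppg_config())
  dt <- suppressWarnings(
    segment_stream_dynamic(sim$stream, tpl, ppg_config(k = 1)))
  expect_identical(dt$fiducials, st$fiducials)
  expect_identical(lapply(dt$cycles, `[`, c("start", "end", "dtw_distance")),
                   lapply(st$cycles, `[`, c("start", "end", "dtw_distance")))
  expect_equal(length(dt$ensemble$templates), 1)
})

test_that("ensemble size never exceeds k across a morphology switch", {
  presets <- ppg_presets()
  spec <- simulation_spec(60, 300, 66, am_depth = 0.1, bw_depth = 0.1,
                          fm_depth = 0.05, noise_sd = 0.015, seed = 6,
                          morphology_schedule = list(
                            list(time_s = 0, model = presets$classic),
                            list(time_s = 30, model = presets$steep_upstroke)))
  sim <- simulate_ppg(spec)
  pspec <- quiet_spec(10, seed = 6)
  tpl <- make_prime_template(pspec)
  dt <- suppressWarnings(
    segment_stream_dynamic(sim$stream, tpl, ppg_config(k = 2)))
  expect_lte(length(dt$ensemble$templates), 2)
  usage <- vapply(dt$ensemble$templates, `[[`, integer(1), "usage_count")
  expect_true(all(usage >= 0))
  expect_gte(length(dt$cycles), 10)
})
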