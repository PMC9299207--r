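test_that("event matching is one-to-one within tolerance", {
  m <- match_events(c(1, 2, 3), c(1, 2, 3), tolerance_ms = 30)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))

  m2 <- match_events(1.005, 1.0, tolerance_ms = 30)
  expect_equal(m2$tp, 1)

  m3 <- match_events(c(0.995, 1.005), 1.0, tolerance_ms = 30)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 1, 0))  # one TP, one FP

  m4 <- match_events(2.0, 1.0, tolerance_ms = 30)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 1, 1))
})

test_that("matching counts are symmetric under prediction/truth swap", {
  set.seed(9)
  pred <- sort(runif(25, 0, 30))
  truth <- sort(runif(20, 0, 30))
  a <- match_events(pred, truth, 50)
  b <- match_events(truth, pred, 50)
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
})

test_that("precision/recall/F1 match hand-computed confusion sets", {
  m <- list(tp = 9, fp = 1, fn = 3)
  met <- classification_metrics(m)
  expect_equal(unname(met["precision"]), 0.9)
  expect_equal(unname(met["recall"]), 0.75)
  expect_equal(unname(met["f1"]), 2 * 0.9 * 0.75 / 1.65)

  expect_equal(unname(classification_metrics(list(tp = 5, fp = 0, fn = 0))),
               c(1, 1, 1))
  met0 <- classification_metrics(list(tp = 0, fp = 2, fn = 3))
  expect_equal(unname(met0["precision"]), 0)
  expect_equal(unname(met0["recall"]), 0)
  expect_true(is.na(met0["f1"]))
  expect_true(is.na(classification_metrics(list(tp = 0, fp = 0, fn = 3))["precision"]))
})

test_that("timestamp RMSE uses matched pairs only", {
  m <- match_events(c(1.01, 1.99), c(1.0, 2.0), tolerance_ms = 30)
  expect_equal(timestamp_rmse(m), 10, tolerance = 1e-9)
  exact <- match_events(1:5, 1:5, 30)
  expect_equal(timestamp_rmse(exact), 0)
  none <- match_events(numeric(0), 1:3, 30)
  expect_error(timestamp_rmse(none), "no positive predictions")
})

test_that("IBI derivation anchors at the later beat in milliseconds", {
  ib <- ibi_from_fiducials(c(1.0, 1.8), "SYS")
  expect_equal(ib$values, 800)
  expect_equal(ib$anchor_timestamps, 1.8)
  ib2 <- ibi_from_fiducials(seq(0, 5, by = 0.5))
  expect_length(ib2$values, 10)
  expect_error(ibi_from_fiducials(c(2, 1)), "increasing")
  expect_error(ibi_from_fiducials(1.5), "at least 2")
})

test_that("plausibility filter keeps IBIs in [300, 1500] ms exactly", {
  ib <- structure(list(values = c(250, 800, 1600),
                       anchor_timestamps = c(1, 2, 3.6),
                       source_label = "SYS"), class = "ibi_series")
  kept <- plausibility_filter(ib)
  expect_equal(kept$values, 800)
  expect_equal(kept$anchor_timestamps, 2)
  all_in <- structure(list(values = c(300, 1000, 1500),
                           anchor_timestamps = 1:3, source_label = "SYS"),
                      class = "ibi_series")
  expect_equal(plausibility_filter(all_in)$values, c(300, 1000, 1500))
  empty <- structure(list(values = numeric(0),
                          anchor_timestamps = numeric(0),
                          source_label = "SYS"), class = "ibi_series")
  expect_length(plausibility_filter(empty)$values, 0)
})

test_that("IBI agreement pairs by anchor time and scores MAE/correlation", {
  ts <- cumsum(c(1, 0.9, 1.1, 0.95, 1.05, 1.0, 0.9))
  truth <- ibi_from_fiducials(ts)
  expect_equal(ibi_agreement(truth, truth)$mae_ms, 0)
  expect_equal(ibi_agreement(truth, truth)$pearson_r, 1)

  shifted <- truth
  shifted$values <- truth$values + 10
  ag <- ibi_agreement(shifted, truth)
  expect_equal(ag$mae_ms, 10)
  expect_equal(ag$pearson_r, 1)  # correlation is shift-invariant

  far <- truth
  far$anchor_timestamps <- truth$anchor_timestamps + 100
  ag2 <- ibi_agreement(far, truth)
  expect_equal(ag2$n_pairs, 0)
  expect_true(is.na(ag2$mae_ms))
})

test_that("per-class and per-source reports assemble correctly", {
  truth <- fiducial_points(index = c(10L, 40L, 70L, 100L),
                           timestamp = c(10, 40, 70, 100) / 100,
                           label = c("EP", "SYS", "EP", "SYS"))
  rep <- evaluate_fiducials(truth, truth, tolerance_ms = 30)
  expect_equal(rep$f1[rep$label == "EP"], 1)
  expect_equal(rep$rmse_ms[rep$label == "SYS"], 0)
  expect_equal(rep$tp[rep$label == "MS"], 0)

  ib <- evaluate_ibi(truth, truth_beats = c(0.1, 0.7, 1.4))
  expect_equal(ib$source, c("EP", "MS", "SYS"))
  expect_equal(ib$n[ib$source == "MS"], 0)
})
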