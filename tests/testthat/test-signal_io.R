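test_that("read_signal handles two-column, one-column and malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,1.0", "0.00333,1.1", "0.00667,1.2"), f)
  s <- read_signal(f)
  expect_length(s$samples, 3)
  expect_equal(s$fs, 300, tolerance = 0.01)
  expect_equal(s$samples, c(1.0, 1.1, 1.2))

  writeLines(c("1.0", "1.1", "1.2"), f)
  s1 <- read_signal(f, fs = 300)
  expect_equal(stream_times(s1), c(0, 1, 2) / 300)
  expect_error(read_signal(f), "fs is required")

  writeLines(c("0.0,1.0", "0.003,abc"), f)
  expect_error(read_signal(f), "parse error")
  writeLines(character(0), f)
  expect_error(read_signal(f), "empty")
})

test_that("signal write/read round-trips", {
  s <- signal_stream(sin(1:500 / 10), fs = 250, t0 = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal(s, f)
  s2 <- read_signal(f)
  expect_equal(s2$samples, s$samples, tolerance = 1e-7)
  expect_equal(s2$fs, s$fs, tolerance = 1e-4)
  expect_equal(s2$t0, 2, tolerance = 1e-6)
})

test_that("signal_stream rejects degenerate input", {
  expect_error(signal_stream(numeric(0), 300), "non-empty")
  expect_error(signal_stream(c(1, NA), 300), "NA")
  expect_error(signal_stream(c(1, Inf), 300), "NA|finite")
  expect_error(signal_stream(1:5, -1), "fs")
})

test_that("bandpass_filter attenuates drift, preserves in-band tones, zero-phase", {
  fs <- 300
  t <- (0:(fs * 40 - 1)) / fs
  drift <- signal_stream(sin(2 * pi * 0.05 * t), fs)
  out <- bandpass_filter(drift, 0.5, 5, 4)
  mid <- seq(fs * 5, fs * 35)  # ignore filter edges
  atten <- 20 * log10(sd(out$samples[mid]) / sd(drift$samples[mid]))
  expect_lt(atten, -20)

  tone <- signal_stream(sin(2 * pi * 1 * t), fs)
  out1 <- bandpass_filter(tone, 0.5, 5, 4)
  expect_equal(sd(out1$samples[mid]), sd(tone$samples[mid]), tolerance = 0.05)
  # zero phase: in-band tone peaks are not shifted (compare within one cycle)
  one <- seq(fs * 10, fs * 11)
  expect_lte(abs(which.max(tone$samples[one]) - which.max(out1$samples[one])),
             1)

  expect_error(bandpass_filter(tone, 4, 3), "low < high")
  expect_error(bandpass_filter(tone, 0.5, 200), "Nyquist")
})

test_that("bandpass_filter is near-idempotent on band-limited input", {
  fs <- 300
  t <- (0:(fs * 30 - 1)) / fs
  s <- signal_stream(sin(2 * pi * 1.3 * t) + 0.4 * sin(2 * pi * 2.6 * t), fs)
  once <- bandpass_filter(s, 0.5, 5, 4)
  twice <- bandpass_filter(once, 0.5, 5, 4)
  mid <- seq(fs * 5, fs * 25)
  rel <- sd(twice$samples[mid] - once$samples[mid]) / sd(once$samples[mid])
  expect_lt(rel, 0.01)
})

test_that("first_derivative scales per batch with deterministic degenerate case", {
  expect_equal(first_derivative(signal_stream(c(0, 2, 1), 10)), c(1, 0, 0))
  expect_warning(
    d <- first_derivative(signal_stream(c(0, 1, 2, 3), 10)),
    "degenerate")
  expect_equal(d, rep(1, 4))
  # sinusoid: max slope at the ascending zero crossing
  fs <- 300
  x <- sin(2 * pi * (0:(fs - 1)) / fs)
  d <- first_derivative(signal_stream(x, fs))
  expect_lte(which.max(d), 2)  # ascending crossing at phase 0
  expect_error(first_derivative(signal_stream(1, 300)), "short")
})

test_that("annotations write/read round-trip with 0-based on-disk indices", {
  pts <- fiducial_points(index = c(301L, 400L), timestamp = c(1.0, 1.33),
                         label = c("SYS", "EP"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(pts, f)
  lines <- readLines(f)
  expect_equal(lines[1], "timestamp_s,sample_index,label")
  expect_equal(lines[2], "1.000000,300,SYS")
  expect_equal(read_annotations(f), pts)

  write_annotations(fiducial_points(), f)
  expect_equal(readLines(f), "timestamp_s,sample_index,label")
  expect_error(write_annotations(pts[2:1, ], f), "sorted")
  expect_error(fiducial_points(1, 0.1, "XX"), "labels")
})

test_that("templates round-trip through CSV + JSON sidecar", {
  tpl <- annotated_template(sin(1:100 / 10) + 2, fs = 300, onset_idx = 1,
                            ms_idx = 10, sys_idx = 20, id = "t1")
  base <- file.path(withr::local_tempdir(), "tpl")
  write_template(tpl, base)
  tpl2 <- read_template(base)
  expect_equal(tpl2$samples, tpl$samples, tolerance = 1e-7)
  expect_equal(tpl2[c("onset_idx", "ms_idx", "sys_idx", "id")],
               tpl[c("onset_idx", "ms_idx", "sys_idx", "id")])
  expect_error(annotated_template(1:50, 300, 10, 5, 20), "onset < max-slope")
})
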