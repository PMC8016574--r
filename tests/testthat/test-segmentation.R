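test_that("instantaneous energy squares the signal", {
  expect_equal(instantaneous_energy(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(instantaneous_energy(c(1, -2, 3)), c(1, 4, 9))
  withr::with_seed(1, x <- rnorm(100))
  expect_equal(sum(instantaneous_energy(x)), sum(x^2))
  expect_error(instantaneous_energy(numeric(0)), "non-empty")
})

test_that("moving-average energy implements the forward window", {
  expect_equal(as.numeric(moving_average_energy(rep(3, 10), 4)), rep(3, 7))
  out <- moving_average_energy(c(0, 0, 4, 4), 2)
  expect_equal(as.numeric(out), c(0, 2, 4))
  expect_equal(attr(out, "window_len"), 2L)
  withr::with_seed(2, e <- runif(200))
  ma <- as.numeric(moving_average_energy(e, 16))
  expect_length(ma, 200 - 16 + 1)
  expect_true(all(ma >= min(e) - 1e-12 & ma <= max(e) + 1e-12))
  expect_error(moving_average_energy(1:3, 4), "exceeds")
})

test_that("threshold is the stated fraction of the maximum", {
  ema <- c(1, 100, 7)
  expect_equal(compute_threshold(ema, 0.02), 2)
  expect_warning(t0 <- compute_threshold(rep(0, 5), 0.02), "zero")
  expect_equal(t0, 0)
  # homogeneity: scaling the sequence scales the threshold
  expect_equal(compute_threshold(3.7 * ema, 0.02),
               3.7 * compute_threshold(ema, 0.02))
  expect_error(compute_threshold(ema, 1.5), "\\(0, 1\\)")
})

test_that("detector matches the exhaustive-scan oracle on a rectangular burst", {
  x <- make_burst_signal(3000L, 1000L, 2000L, burst_amp = 1,
                         baseline_amp = 0.01, seed = 5)
  cfg <- segmenter_config(window_len = 128L)
  ema <- moving_average_energy(instantaneous_energy(x), cfg$window_len)
  thr <- compute_threshold(ema, cfg$threshold_fraction)
  seg <- detect_active_segments(ema, thr, cfg)
  expect_equal(nrow(seg), 1L)
  expect_lte(abs(seg$start - 1000L), 128L)
  expect_lte(abs(seg$end - 2000L), 128L)
  oracle <- oracle_scan_segments(as.numeric(ema), thr, cfg$window_len)
  expect_equal(seg$start, oracle$start)
  expect_equal(seg$end, oracle$end)
})

test_that("two separated bursts yield two ordered segments agreeing with the oracle", {
  withr::with_seed(9, {
    x <- 0.01 * sample(c(-1, 1), 6000, replace = TRUE)
    x[1001:1800] <- sample(c(-1, 1), 800, replace = TRUE)
    x[4001:4900] <- sample(c(-1, 1), 900, replace = TRUE)
  })
  cfg <- segmenter_config()
  ema <- moving_average_energy(instantaneous_energy(x), cfg$window_len)
  thr <- compute_threshold(ema, cfg$threshold_fraction)
  seg <- detect_active_segments(ema, thr, cfg)
  expect_equal(nrow(seg), 2L)
  expect_true(all(diff(seg$start) > 0))
  expect_true(all(seg$end[-nrow(seg)] <= seg$start[-1]))
  oracle <- oracle_scan_segments(as.numeric(ema), thr, cfg$window_len)
  expect_equal(seg$start, oracle$start)
  expect_equal(seg$end, oracle$end)
})

test_that("all-subthreshold sequences give no segments; zero record is empty", {
  cfg <- segmenter_config(window_len = 8L)
  seg <- detect_active_segments(rep(0.01, 100), 0.5, cfg)
  expect_equal(nrow(seg), 0L)
  rec <- signal_record(matrix(0, 1000, 1), fs = 1000, channel_names = "e")
  expect_warning(seg0 <- segment_record(rec, cfg, "e"), "zero")
  expect_equal(nrow(seg0), 0L)
})

test_that("segment_record equals the manual chain of the three operations", {
  x <- make_burst_signal(seed = 11)
  rec <- signal_record(matrix(x), fs = 1000, channel_names = "emg")
  cfg <- segmenter_config()
  got <- segment_record(rec, cfg, "emg")
  ema <- moving_average_energy(instantaneous_energy(x), cfg$window_len)
  want <- detect_active_segments(ema, compute_threshold(ema, cfg$threshold_fraction),
                                 cfg, channel = "emg")
  expect_identical(got, want)
  expect_error(segment_record(rec, cfg, "nope"), "unknown channel")
})

test_that("detection is invariant to positive amplitude scaling", {
  x <- make_burst_signal(seed = 13)
  cfg <- segmenter_config()
  rec1 <- signal_record(matrix(x), fs = 1000, channel_names = "e")
  rec2 <- signal_record(matrix(250 * x), fs = 1000, channel_names = "e")
  expect_identical(segment_record(rec1, cfg, "e"), segment_record(rec2, cfg, "e"))
})

test_that("segments stay disjoint, sorted and in bounds on random burst trains", {
  cfg <- segmenter_config()
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- 8000L
      x <- 0.01 * rnorm(n)
      n_bursts <- sample(1:3, 1)
      starts <- sort(sample(seq(500L, n - 1500L, by = 100L), n_bursts))
      for (b in starts) x[b:(b + 700L)] <- rnorm(701)
    })
    rec <- signal_record(matrix(x), fs = 1000, channel_names = "e")
    seg <- suppressWarnings(segment_record(rec, cfg, "e"))
    if (nrow(seg) > 1) {
      expect_true(all(diff(seg$start) > 0))
      expect_true(all(seg$end[-nrow(seg)] <= seg$start[-1]))
    }
    expect_true(all(seg$start >= 0 & seg$end <= n))
    expect_true(all(seg$end > seg$start))
  }
})

test_that("high-contrast bursts are recovered within a window of the oracle", {
  cfg <- segmenter_config()
  for (s in 1:15) {
    withr::with_seed(s + 100, {
      b0 <- sample(500:4000, 1)
      len <- sample(600:1500, 1)
    })
    x <- make_burst_signal(6000L, b0, b0 + len, burst_amp = 1,
                           baseline_amp = 0.05, seed = s)
    ema <- moving_average_energy(instantaneous_energy(x), cfg$window_len)
    thr <- compute_threshold(ema, cfg$threshold_fraction)
    seg <- suppressWarnings(detect_active_segments(ema, thr, cfg))
    oracle <- oracle_scan_segments(as.numeric(ema), thr, cfg$window_len)
    expect_equal(nrow(seg), 1L)
    expect_lte(abs(seg$start - oracle$start[1]), cfg$window_len)
    expect_lte(abs(seg$end - oracle$end[1]), cfg$window_len)
  }
})
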