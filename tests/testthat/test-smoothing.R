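# Fractional-window moving average and the smoothed estimators.

test_that("smoothing_window brackets fractional k", {
  w <- smoothing_window(10.4)
  expect_identical(c(w$k1, w$k2), c(10L, 11L))
  expect_equal(w$w1, 1 / 0.4)
  expect_equal(w$w2, 1 / 0.6)
  expect_null(smoothing_window(7)$w1)
  expect_error(smoothing_window(1), "> 1")
})

test_that("moving_average matches hand-computed windows and edge policy", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3), c(NA, 2, 3, 4, NA))
  # even k: endpoints at +-k/2 weighted 1/(2k), interior 1/k
  expect_equal(moving_average(c(0, 4, 0), 2)[2], 2)
  # constant input stays constant at interior positions
  sm <- moving_average(rep(3.3, 40), 10.4)
  expect_equal(sm[6:35], rep(3.3, 30))
  expect_true(all(is.na(sm[c(1:5, 36:40)])))
  expect_error(moving_average(rep(NA_real_, 10), 3), "all-missing")
})

test_that("kernel weights sum to one for odd, even and fractional k", {
  ones <- rep(1, 60)
  for (k in c(3, 7, 4, 10, 2.5, 9.7, 10.4)) {
    sm <- moving_average(ones, k)
    expect_equal(sm[!is.na(sm)], rep(1, sum(!is.na(sm))), tolerance = 1e-12)
  }
})

test_that("moving_average is linear and shift-equivariant", {
  set.seed(21)
  x <- rnorm(200); y <- rnorm(200)
  for (k in c(5, 8, 10.4)) {
    expect_equal(moving_average(2 * x - 3 * y, k),
                 2 * moving_average(x, k) - 3 * moving_average(y, k))
  }
  shifted <- moving_average(c(rep(NA, 7), x), 10.4)
  expect_equal(shifted[-(1:7)], moving_average(x, 10.4))
})

test_that("missing values propagate through the window, no imputation", {
  x <- c(1, 2, NA, 4, 5, 6, 7, 8, 9)
  sm <- moving_average(x, 3)
  expect_true(all(is.na(sm[2:4])))
  expect_equal(sm[5:8], c(5, 6, 7, 8))
})

test_that("an odd-k window annihilates a sinusoid of period k", {
  x <- sin(2 * pi * seq_len(200) / 11)
  sm <- moving_average(x, 11)
  expect_lt(max(abs(sm), na.rm = TRUE), 1e-12)
})

test_that("k = 10.4 attenuates the helical-repeat sinusoid below 0.5%", {
  # direct-evaluation oracle: residual amplitude of the combined k=10/k=11
  # kernel on a period-10.4 sinusoid (any phase)
  for (phase in c(0, 0.7, 2.1)) {
    x <- sin(2 * pi * seq_len(400) / 10.4 + phase)
    sm <- moving_average(x, 10.4)
    expect_lt(max(abs(sm), na.rm = TRUE), 0.005)
  }
  # the kernel's own prediction is ~0.13%
  x <- sin(2 * pi * seq_len(2000) / 10.4)
  expect_lt(max(abs(moving_average(x, 10.4)), na.rm = TRUE), 0.002)
})

test_that("moving_average on a track preserves coordinates", {
  tr <- position_track(rnorm(50), "chrII", 25)
  sm <- moving_average(tr, 10.4)
  expect_s3_class(sm, "position_track")
  expect_identical(sm$chrom, "chrII")
  expect_identical(track_positions(sm), track_positions(tr))
})

test_that("c0s_estimate averages co-registered tracks with NA propagation", {
  t1 <- position_track(c(1, 2, 3), "c", 10)
  expect_equal(c0s_estimate(list(t1, t1, t1))$values, t1$values)
  tn <- position_track(-t1$values, "c", 10)
  expect_equal(c0s_estimate(list(t1, t1, t1, tn, tn, tn))$values, c(0, 0, 0))
  tna <- position_track(c(1, NA, 3), "c", 10)
  expect_equal(is.na(c0s_estimate(list(t1, tna))$values), c(FALSE, TRUE, FALSE))
  expect_error(c0s_estimate(list(t1, position_track(1:3, "c", 11))),
               "co-registered")
  expect_error(c0s_estimate(list(t1)), "at least two")
  # commutes with adding a common constant
  tc <- position_track(t1$values + 5, "c", 10)
  expect_equal(c0s_estimate(list(tc, tc))$values,
               c0s_estimate(list(t1, t1))$values + 5)
})

test_that("six-track estimator beats any single smoothed track on simulation", {
  res <- small_sim("i")
  c0 <- res$truth$c0
  sm <- lapply(res$observed, moving_average, k = 10.4)
  single <- vapply(sm, function(s) cor(s, c0, use = "complete.obs"), numeric(1))
  avg <- c0s_estimate(lapply(sm, position_track))
  expect_gte(cor(avg$values, c0, use = "complete.obs"), max(single))
})

test_that("window_consistency_scan finds the helical repeat", {
  # identical tracks are perfectly consistent at every k
  tr <- position_track(rnorm(500), "c", 1)
  sc <- window_consistency_scan(list(tr, tr), c(2, 7, 10.4))
  expect_equal(sc$mean_cor, rep(1, 3))
  # two antiphase sinusoids, unsmoothed (k = 1): correlation -1
  a <- sinusoid_track(300)
  b <- sinusoid_track(300, phase = pi)
  expect_equal(window_consistency_scan(list(a, b), 1)$mean_cor, -1,
               tolerance = 1e-8)
  # simulated setting (i): consistency peaks near k = 10.4
  res <- small_sim("i")
  tracks <- lapply(res$observed, position_track)
  sc <- window_consistency_scan(tracks, c(7, 10.4, 14))
  expect_gt(sc$mean_cor[sc$k == 10.4], sc$mean_cor[sc$k == 7])
  expect_gt(sc$mean_cor[sc$k == 10.4], sc$mean_cor[sc$k == 14])
  expect_error(window_consistency_scan(list(tr), c(2, 3)), "two tracks")
})

test_that("local_amplitude recovers sinusoid amplitude by half-range", {
  expect_equal(unique(na.omit(local_amplitude(rep(2.2, 30), 5))), 0)
  for (phase in seq(0, 2 * pi, length.out = 7)) {
    x <- 3 * sin(2 * pi * seq_len(120) / 10.4 + phase)
    amp <- local_amplitude(x, 5)
    interior <- amp[!is.na(amp)]
    expect_true(all(interior >= 0.95 * 3 & interior <= 3 + 1e-9))
  }
  # slowly varying baseline barely inflates the estimate
  x <- 0.002 * seq_len(200) + 2 * sin(2 * pi * seq_len(200) / 10.4)
  interior <- na.omit(local_amplitude(x, 5))
  expect_true(all(abs(interior - 2) < 0.1))
})

test_that("amplitude_ratio_track divides co-registered tracks", {
  a <- position_track(c(1, 2, 4), "c", 1)
  expect_equal(amplitude_ratio_track(a, a)$values, rep(1, 3))
  b <- position_track(a$values / 0.7, "c", 1)
  expect_equal(amplitude_ratio_track(a, b)$values, rep(0.7, 3))
  z <- position_track(c(1, 0, 4), "c", 1)
  expect_true(is.na(amplitude_ratio_track(a, z)$values[2]))
  expect_error(amplitude_ratio_track(a, position_track(1:3, "d", 1)),
               "co-registered")
})

test_that("local amplitude ratio tracks the generated ratio in setting (iii)", {
  # noise-free world isolates the half-range estimator itself
  res <- simulate_setting(
    simulation_setting("iii", length = 20000L, noise_sd = 0, seed = 5L))
  amp26 <- local_amplitude(res$observed$c26 - res$truth$c0, 5)
  amp31 <- local_amplitude(res$observed$c31 - res$truth$c0, 5)
  ratio <- amp26 / amp31
  truth <- res$truth$a26 / res$truth$a31
  ok <- !is.na(ratio)
  # median relative error within 10%
  expect_lt(median(abs(ratio[ok] / truth[ok] - 1)), 0.10)
})
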