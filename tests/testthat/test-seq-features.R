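# Sequence diagnostics: quartiles, dinucleotide and poly(dA:dT) profiles,
# lagged correlations, spectra, dyad alignment and Q(f) tuning.

test_that("sequence_set validates its records", {
  s <- sequence_set("a", paste0(strrep("acgt", 12), "ac"), 1)
  expect_equal(nchar(s$sequence), 50)
  expect_true(grepl("^[ACGT]+$", s$sequence))
  expect_error(sequence_set(c("a", "b"), c("ACGT", "ACG")), "same length")
  expect_error(sequence_set("a", "ACGX"), "alphabet")
})

test_that("quartile_split takes floor(N/4) with stable ties", {
  set <- sequence_set(letters[1:8], rep(strrep("A", 10), 8), score = 1:8)
  qs <- quartile_split(set)
  expect_setequal(qs$top$score, c(8, 7))
  expect_setequal(qs$bottom$score, c(1, 2))
  # ties: earliest input records win in both groups
  tied <- sequence_set(letters[1:8], rep(strrep("A", 10), 8), score = rep(1, 8))
  qt <- quartile_split(tied)
  expect_identical(qt$top$id, c("a", "b"))
  expect_identical(qt$bottom$id, c("a", "b"))
  expect_error(quartile_split(set[1:3, ]), "at least 4")
})

test_that("dinuc_ww_frequency counts AA/AT/TA/TT starts per position", {
  one <- sequence_set("x", paste0("AATT", strrep("G", 46)))
  prof <- dinuc_ww_frequency(one)
  expect_equal(prof$frequency, c(1, 1, 1, rep(0, 46)))
  gc <- sequence_set("y", strrep("GC", 25))
  expect_equal(dinuc_ww_frequency(gc)$frequency, rep(0, 49))
  two <- sequence_set(c("a", "b"),
                      c(paste0("AA", strrep("G", 48)),
                        paste0("GG", strrep("G", 48))))
  expect_equal(dinuc_ww_frequency(two)$frequency[1], 0.5)
  # N never matches
  nn <- sequence_set("n", paste0("AN", strrep("G", 48)))
  expect_equal(dinuc_ww_frequency(nn)$frequency[1], 0)
})

test_that("WW profile is reverse-complement symmetric", {
  set.seed(13)
  seqs <- vapply(1:40, function(i) {
    paste0(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  }, "")
  set <- sequence_set(as.character(1:40), seqs)
  rc <- sequence_set(set$id, reverse_complement(set$sequence))
  expect_equal(dinuc_ww_frequency(set)$frequency,
               rev(dinuc_ww_frequency(rc)$frequency))
})

test_that("profiles of a union are record-weighted means of the parts", {
  a <- sequence_set(as.character(1:3), c("AATT", "GGCC", "ATAT"))
  b <- sequence_set("4", "TTTT")
  u <- sequence_set(as.character(1:4), c(a$sequence, b$sequence))
  fu <- dinuc_ww_frequency(u)$frequency
  expect_equal(fu, (3 * dinuc_ww_frequency(a)$frequency +
                    1 * dinuc_ww_frequency(b)$frequency) / 4)
})

test_that("polyat_coverage marks homopolymeric A/T runs only", {
  one <- sequence_set("x", paste0("GG", "AAAA", strrep("G", 44)))
  cov <- polyat_coverage(one)$coverage
  expect_equal(which(cov == 1), 3:6)
  expect_equal(sum(cov), 4)
  # alternating AT never qualifies under the homopolymer rule
  alt <- sequence_set("y", strrep("AT", 25))
  expect_equal(polyat_coverage(alt)$coverage, rep(0, 50))
  allt <- sequence_set("z", strrep("T", 50))
  expect_equal(polyat_coverage(allt)$coverage, rep(1, 50))
  # runs shorter than min_len do not count
  short <- sequence_set("w", paste0("AAA", strrep("G", 47)))
  expect_equal(sum(polyat_coverage(short, 4)$coverage), 0)
  expect_equal(sum(polyat_coverage(short, 3)$coverage), 3)
  expect_error(polyat_coverage(one, min_len = 1), ">= 2")
})

test_that("lagged correlations behave on constructed signals", {
  x <- sin(2 * pi * seq_len(400) / 10.4)
  expect_equal(autocorrelation(x, 0)$r, 1)
  shifted <- c(rep(NA, 5), x)[1:400]
  cc <- cross_correlation(x, shifted, 8)
  expect_equal(cc$lag[which.max(cc$r)], 5)
  expect_error(cross_correlation(x[1:20], x[1:20], 2), "overlapping")
})

test_that("power spectrum satisfies Parseval and finds planted periods", {
  x <- rep(4.2, 100)
  expect_error(power_spectrum(x[1:10]), "64")
  sp <- power_spectrum(x)
  expect_equal(max(sp$power), 0, tolerance = 1e-18)
  set.seed(2)
  y <- rnorm(512)
  sp <- power_spectrum(y)
  # total periodogram power equals the summed squared deviations
  full <- sum(Mod(fft(y - mean(y)))^2) / length(y)
  expect_equal(2 * sum(sp$power) + 0, full, tolerance = 0.05 * full)
  z <- sin(2 * pi * seq_len(16384) / 10.4)
  expect_gte(peak_period(power_spectrum(z), c(8, 13)), 10.3)
  expect_lte(peak_period(power_spectrum(z), c(8, 13)), 10.5)
  expect_error(peak_period(power_spectrum(z), c(1e7, 2e7)), "band")
})

test_that("dyad_profile averages centered windows and skips edge dyads", {
  tr <- position_track(rep(1.5, 300), "c", 1)
  pr <- dyad_profile(tr, c(100, 200), flank = 20)
  expect_equal(pr$mean, rep(1.5, 41))
  expect_equal(pr$n, rep(2, 41))
  # single dyad returns the window verbatim
  tr2 <- position_track(seq_len(300) * 1.0, "c", 1)
  pr2 <- dyad_profile(tr2, 150, flank = 10)
  expect_equal(pr2$mean, 140:160)
  # dyads too close to the edge are skipped and counted
  pr3 <- dyad_profile(tr2, c(5, 150), flank = 10)
  expect_identical(attr(pr3, "skipped"), 1L)
  expect_error(dyad_profile(tr2, 5, flank = 10), "no dyad")
})

test_that("phase-locked dyads reveal tether bias that c0s removes", {
  fx <- the_fixture()
  raw <- dyad_profile(fx$tracks$c26_f, fx$dyads, flank = 50)
  est <- dyad_profile(fixture_c0s(), fx$dyads, flank = 50)
  amp <- function(pr) sqrt(cycliz:::.band_power(pr$mean, c(9, 12)))
  expect_gte(amp(raw) / amp(est), 10)
})

test_that("tune_amplitude_ratio recovers the planted f = 0.7", {
  lib <- make_tune_library()
  tn <- tune_amplitude_ratio(lib, f_grid = c(0.3, 0.5, 0.7, 1.0, 1.4))
  expect_equal(tn$f, 0.7)
  expect_true(tn$stable)
  single <- tune_amplitude_ratio(lib, f_grid = 0.9)
  expect_equal(single$f, 0.9)
})

test_that("tune_amplitude_ratio flags a signal-free library as unstable", {
  rnd <- make_random_library()
  expect_warning(
    tn <- tune_amplitude_ratio(rnd, c(0.3, 0.7, 1.4), top_n = 500),
    "unstable")
  expect_false(tn$stable)
})

test_that("wrong-ratio quartiles show WW periodicity, c0s quartiles do not", {
  fx <- the_fixture()
  lib <- fx$library
  wrong <- solve_c0_table(lib$c26, lib$c29, lib$c31,
                          amplitude_ratio_scheme(1.4))$c0
  est <- fixture_c0s()
  centers <- attr(lib, "centers")
  good <- est$values[centers - est$origin + 1L]
  bp_wrong <- top_quartile_ww_band_power(
    sequence_set(lib$id, lib$sequence, wrong))
  bp_good <- top_quartile_ww_band_power(
    sequence_set(lib$id, lib$sequence, good))
  expect_gte(bp_wrong / bp_good, 5)
})
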