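# Shared in-code fixtures.  Everything is generated at test time; nothing is
# stored on disk.

# sinusoid track of given amplitude/period/phase
sinusoid_track <- function(n, amplitude = 1, period = 10.4, phase = 0,
                           chrom = "chr", origin = 1L) {
  position_track(amplitude * sin(2 * pi * seq_len(n) / period + phase),
                 chrom, origin)
}

# one small simulated benchmark result, memoised per (label, length, seed)
local_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(label = "i", length = 30000L, seed = 42L) {
  key <- paste(label, length, seed, sep = "_")
  if (is.null(local_sim_cache[[key]])) {
    local_sim_cache[[key]] <- simulate_setting(
      simulation_setting(label, length = length, seed = seed))
  }
  local_sim_cache[[key]]
}

# scored library whose top-ranked A/T periodicity vanishes at f = 0.7:
# each record has a helical phase psi; its WW periodicity strength m drives
# the intrinsic score, and the tether phase is locked to psi, so a wrong f
# lets phase-aligned bias leak into the top set
make_tune_library <- function(n = 4000L, seed = 7L, ratio31 = 0.7) {
  set.seed(seed)
  psi <- runif(n, 0, 2 * pi)
  m <- runif(n)
  c0 <- 1.5 * m + rnorm(n, 0, 0.3)
  a26 <- runif(n, 0.5, 2)
  sch <- amplitude_ratio_scheme(ratio31)
  p <- 1:50
  seqs <- vapply(seq_len(n), function(i) {
    w <- runif(50) < 0.35 + 0.3 * m[i] * cos(2 * pi * p / 10.4 - psi[i])
    paste0(ifelse(w, sample(c("A", "T"), 50, TRUE),
                  sample(c("C", "G"), 50, TRUE)), collapse = "")
  }, "")
  data.frame(id = as.character(seq_len(n)), sequence = seqs,
             c26 = forward_cn(c0, a26, psi, 26, sch),
             c31 = forward_cn(c0, a26, psi, 31, sch),
             stringsAsFactors = FALSE)
}

# uniform random 50-bp sequences with unrelated scores
make_random_library <- function(n = 2000L, seed = 1L) {
  set.seed(seed)
  data.frame(
    id = as.character(seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste0(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    }, ""),
    c26 = rnorm(n), c31 = rnorm(n), stringsAsFactors = FALSE)
}

# the default synthetic fixture, memoised (used across feature/io tests)
the_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- generate_fixture(seed = 2L)
    fx
  }
})

# six-track smoothed estimator for a fixture
fixture_c0s <- local({
  est <- NULL
  function() {
    if (is.null(est)) {
      est <<- c0s_estimate(lapply(the_fixture()$tracks, moving_average, k = 10.4))
    }
    est
  }
})

# band power of the ~10-bp component of the WW profile of a set's top quartile
top_quartile_ww_band_power <- function(set, band = c(9, 12)) {
  prof <- dinuc_ww_frequency(quartile_split(set)$top)$frequency
  cycliz:::.band_power(prof, band)
}
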