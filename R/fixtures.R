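## Synthetic fixture generator.  Builds a small genome with planted,
## diagnosable bendability features -- 10.4-bp-periodic WW dinucleotides on a
## global helical grid (bendable) and homopolymeric poly(dA:dT) tracts
## (stiff) -- derives a designed intrinsic-cyclizability track from those
## features, and emits tether-biased C_n tracks from the forward model for
## both strands, phase-locked dyads and a scored library table.  Everything
## is deterministic given the seed.  This stands in for trained-model C_n
## predictions; it is synthetic by construction and labelled as such.

# rolling amplitude of the `period`-periodic component of a 0/1 dinucleotide
# indicator, over 49-bp windows centered at each position
.ww_periodicity_score <- function(w2, period) {
  p <- seq_along(w2)
  ang <- 2 * pi * p / period
  box <- rep(1, 49)
  sc <- as.numeric(stats::filter(w2 * cos(ang), box, sides = 2))
  ss <- as.numeric(stats::filter(w2 * sin(ang), box, sides = 2))
  sqrt(sc^2 + ss^2) / (49 / period)  # ~1 for one planted WW per helical turn
}

#' Generate a synthetic fixture genome with known answers
#'
#' Builds a random genome partitioned into blocks: "bendable" blocks carry AA
#' or TT dinucleotides planted on a global 10.4-bp helical grid, "stiff"
#' blocks carry homopolymeric poly(dA:dT) tracts, the rest is neutral.  The
#' designed intrinsic cyclizability at window center l is
#' `baseline_walk(l) + bonus * ww_periodicity(S_l) - penalty * polyAT_occupancy(l +- 10)`,
#' computed from the realised sequence, so feature diagnostics have known
#' answers.  Observed C_n tracks for n = 26, 29, 31 on both strands follow
#' the forward tether-bias model with bounded amplitude walks and exact phase
#' progression; the reverse strand gets an independent phase start and is
#' stored mapped to the forward window centers.  Dyads sit on the WW grid
#' (phase-locked).
#'
#' @param genome_length Genome size in bp (default 12000).
#' @param n_library Number of library records sampled from the genome.
#' @param seed Integer master seed (all randomness derives from it).
#' @param period Helical repeat in bp.
#' @param noise_sd Observation noise sd on the C_n tracks.
#' @param bonus,penalty Weights of the periodic-WW and poly(dA:dT) features
#'   in the designed intrinsic cyclizability.
#' @param ratio31 True `A26/A31` ratio used by the forward model.
#' @param out_dir Optional directory: writes `genome.fa`, six `c*_[fr].tsv`
#'   tracks, `c0_truth.tsv`, `dyads.bed` and `library.tsv`.
#' @return List with `genome` (named character), `c0` (truth
#'   [position_track()]), `tracks` (list `c26_f, c29_f, c31_f, c26_r, c29_r,
#'   c31_r`), `dyads` (1-based positions), `library` (a [sequence_set()] with
#'   added columns `c26, c29, c31, c0hat`), and `params`.
#' @export
generate_fixture <- function(genome_length = 12000L, n_library = 3000L,
                             seed = 1L, period = 10.4, noise_sd = 0.1,
                             bonus = 0.6, penalty = 0.8, ratio31 = 0.7,
                             out_dir = NULL) {
  G <- as.integer(genome_length)
  stopifnot(G >= 2000L, n_library >= 4L)
  ss <- .substream_seeds(seed, 12L)
  chrom <- "chrF"
  scheme <- amplitude_ratio_scheme(ratio31, period)

  ## 1. genome with planted features -----------------------------------------
  chars <- .with_seed(ss[1], sample(c("A", "C", "G", "T"), G, replace = TRUE))
  block <- 400L
  n_blocks <- ceiling(G / block)
  btype <- .with_seed(ss[2], sample(c("bendy", "stiff", "neutral"), n_blocks,
                                    replace = TRUE, prob = c(0.4, 0.3, 0.3)))
  grid <- unique(as.integer(round(seq(2, G - 1, by = period))))  # global helical WW grid
  .with_seed(ss[3], {
    for (b in which(btype == "bendy")) {
      lo <- (b - 1L) * block + 1L; hi <- min(b * block, G) - 1L
      g <- grid[grid >= lo & grid <= hi]
      g <- g[runif(length(g)) < 0.9]
      ww <- sample(c("A", "T"), length(g), replace = TRUE)
      chars[g] <- ww; chars[g + 1L] <- ww  # AA or TT on the grid
    }
    for (b in which(btype == "stiff")) {
      lo <- (b - 1L) * block + 1L; hi <- min(b * block, G)
      starts <- seq(lo + 5L, hi - 10L, by = 35L)
      for (s in starts) {
        len <- sample(4:7, 1L)
        chars[s:(s + len - 1L)] <- sample(c("A", "T"), 1L)
      }
    }
  })
  genome <- stats::setNames(paste0(chars, collapse = ""), chrom)

  ## 2. designed intrinsic cyclizability at window centers --------------------
  centers <- (WINDOW_UP + 1L):(G - WINDOW_DOWN)
  W <- chars == "A" | chars == "T"
  w2 <- as.numeric(W[-G] & W[-1L])                       # WW dinucleotide starts
  wwscore <- .ww_periodicity_score(w2, period)[centers]
  occ <- as.numeric(.polyat_mask(chars, 4L))
  polyocc <- as.numeric(stats::filter(occ, rep(1 / 21, 21), sides = 2))[centers]
  # same bounded walk as the simulation benchmark's intrinsic-cyclizability
  baseline <- .with_seed(ss[4], bounded_random_walk(length(centers), 1 / 12, -2, 2))
  c0 <- baseline + bonus * wwscore - penalty * polyocc
  c0_track <- position_track(c0, chrom, centers[1L])

  ## 3. forward-model C_n tracks, both strands --------------------------------
  nL <- length(centers)
  make_strand <- function(seed_a, seed_phi, seed_eps) {
    a26 <- .with_seed(seed_a, bounded_random_walk(nL, 1 / 10, 0.5, 2))
    phi <- .with_seed(seed_phi, runif(1, 0, 2 * pi)) -
      2 * pi * (seq_len(nL) - 1) / period
    eps <- .with_seed(seed_eps, matrix(rnorm(3L * nL, 0, noise_sd), ncol = 3L))
    lapply(stats::setNames(1:3, c("c26", "c29", "c31")), function(j) {
      n <- c(26, 29, 31)[j]
      v <- c0 + (a26 / ratio_at(scheme, n)) * sin(2 * pi * n / period + phi) +
        eps[, j]
      position_track(v, chrom, centers[1L])
    })
  }
  fwd <- make_strand(ss[5], ss[6], ss[7])
  rev <- make_strand(ss[8], ss[9], ss[10])
  tracks <- list(c26_f = fwd$c26, c29_f = fwd$c29, c31_f = fwd$c31,
                 c26_r = rev$c26, c29_r = rev$c29, c31_r = rev$c31)

  ## 4. phase-locked dyads on the WW grid -------------------------------------
  margin <- 200L
  dyads <- grid[seq(1L, length(grid), by = 16L)]
  dyads <- dyads[dyads >= margin & dyads <= G - margin]

  ## 5. library table ----------------------------------------------------------
  lib_centers <- .with_seed(ss[11], sort(sample(centers, n_library)))
  lib <- extract_windows(genome, chrom, lib_centers)
  at <- function(tr) tr$values[lib_centers - tr$origin + 1L]
  lib$score <- at(c0_track)
  lib$c26 <- at(fwd$c26); lib$c29 <- at(fwd$c29); lib$c31 <- at(fwd$c31)
  lib$c0hat <- solve_c0_table(lib$c26, lib$c29, lib$c31, scheme)$c0
  attr(lib, "centers") <- lib_centers

  out <- list(genome = genome, c0 = c0_track, tracks = tracks, dyads = dyads,
              library = lib,
              params = list(genome_length = G, n_library = n_library,
                            seed = seed, period = period, noise_sd = noise_sd,
                            bonus = bonus, penalty = penalty, ratio31 = ratio31))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_track(c0_track, file.path(out_dir, "c0_truth.tsv"))
    for (nm in names(tracks)) {
      write_track(tracks[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    write_dyads_bed(dyads, chrom, file.path(out_dir, "dyads.bed"))
    write_library_table(as.data.frame(lib), file.path(out_dir, "library.tsv"))
  }
  out
}
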