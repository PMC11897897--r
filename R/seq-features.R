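## Sequence- and track-level diagnostics for residual tether bias: quartile
## splits, per-position WW (AA/AT/TA/TT) dinucleotide frequency, poly(dA:dT)
## coverage, lagged correlations, periodograms, dyad-aligned profiles and the
## historical Q(f) ratio-tuning procedure.

#' Fixed-length scored sequence set
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of equal-length sequences over
#'   `A, C, G, T, N` (lowercase accepted, stored uppercase).
#' @param score Numeric scores (default `NA`).
#' @return `data.frame` of class `"sequence_set"` with columns `id`,
#'   `sequence`, `score`.
#' @export
sequence_set <- function(id, sequence, score = NA_real_) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) < 1L) stop("empty sequence set")
  L <- unique(nchar(sequence))
  if (length(L) != 1L) stop("all sequences must have the same length")
  if (any(grepl("[^ACGTN]", sequence))) {
    stop("sequences must use the alphabet A, C, G, T, N")
  }
  out <- data.frame(id = as.character(id), sequence = sequence,
                    score = rep_len(as.numeric(score), length(sequence)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sequence_set", "data.frame")
  out
}

# character matrix (records x positions)
.seq_matrix <- function(set) {
  do.call(rbind, strsplit(set$sequence, "", fixed = TRUE))
}

#' Top/bottom quartile split by score
#'
#' Top quartile = the `floor(N/4)` highest-scoring records, bottom = the
#' `floor(N/4)` lowest; ties are broken by stable input order (earliest
#' records win in both groups).
#'
#' @param set A [sequence_set()] with scores.
#' @return List with elements `top` and `bottom` (both [sequence_set()]).
#' @export
quartile_split <- function(set) {
  stopifnot(inherits(set, "sequence_set"))
  n <- nrow(set)
  if (n < 4L) stop("need at least 4 records for a quartile split")
  q <- n %/% 4L
  top <- set[order(set$score, decreasing = TRUE, method = "radix")[seq_len(q)], ]
  bottom <- set[order(set$score, method = "radix")[seq_len(q)], ]
  class(top) <- class(bottom) <- class(set)
  list(top = top, bottom = bottom)
}

#' Per-position WW dinucleotide frequency
#'
#' At position p (1 .. L-1), the fraction of sequences whose bases (p, p+1)
#' form AA, AT, TA or TT.  Dinucleotides containing N never match.
#'
#' @param set A [sequence_set()].
#' @return `data.frame` with columns `position` (1 .. L-1) and `frequency`.
#' @export
dinuc_ww_frequency <- function(set) {
  stopifnot(inherits(set, "sequence_set"), nrow(set) >= 1L)
  m <- .seq_matrix(set)
  W <- m == "A" | m == "T"
  L <- ncol(m)
  ww <- W[, -L, drop = FALSE] & W[, -1L, drop = FALSE]
  data.frame(position = seq_len(L - 1L), frequency = colMeans(ww))
}

# logical vector: position inside a homopolymeric A- or T-run of length >= min_len
.polyat_mask <- function(chars, min_len) {
  r <- rle(chars)
  keep <- (r$values == "A" | r$values == "T") & r$lengths >= min_len
  rep(keep, r$lengths)
}

#' Poly(dA:dT) tract coverage profile
#'
#' A position is covered in a sequence iff it lies inside a maximal
#' homopolymeric run of A's, or of T's, of length >= `min_len` (mixed A/T
#' runs do not qualify; N never counts).  Returns the per-position covered
#' fraction across the set.
#'
#' @param set A [sequence_set()].
#' @param min_len Minimum qualifying run length (>= 2, default 4).
#' @return `data.frame` with columns `position` and `coverage` in \[0, 1\].
#' @export
polyat_coverage <- function(set, min_len = 4L) {
  stopifnot(inherits(set, "sequence_set"))
  if (min_len < 2L) stop("`min_len` must be >= 2")
  m <- .seq_matrix(set)
  cov <- t(apply(m, 1L, .polyat_mask, min_len = min_len))
  if (ncol(m) == 1L) cov <- t(cov)
  data.frame(position = seq_len(ncol(m)), coverage = colMeans(cov))
}

.lagged_cor <- function(a, b, max_lag, min_overlap = 30L) {
  a <- if (inherits(a, "position_track")) a$values else as.numeric(a)
  b <- if (inherits(b, "position_track")) b$values else as.numeric(b)
  n <- min(length(a), length(b))
  vapply(0:max_lag, function(k) {
    ai <- a[(1L + k):n]; bi <- b[1L:(n - k)]
    ok <- !is.na(ai) & !is.na(bi)
    if (sum(ok) < min_overlap) stop("fewer than ", min_overlap,
                                    " overlapping positions at lag ", k)
    cor(ai[ok], bi[ok])
  }, numeric(1))
}

#' Lagged auto- and cross-correlation of tracks
#'
#' `cross_correlation()` reports the Pearson correlation of `a(i + k)` with
#' `b(i)` for non-negative lags `k = 0 .. max_lag`; `autocorrelation()` is the
#' `a = b` case.  At least 30 jointly non-missing positions are required per
#' lag.
#'
#' @param a,b Tracks ([position_track()]) or numeric vectors.
#' @param track Track for `autocorrelation()`.
#' @param max_lag Maximum lag in bp.
#' @return `data.frame` with columns `lag` and `r`.
#' @export
cross_correlation <- function(a, b, max_lag) {
  data.frame(lag = 0:max_lag, r = .lagged_cor(a, b, max_lag))
}

#' @rdname cross_correlation
#' @export
autocorrelation <- function(track, max_lag) {
  cross_correlation(track, track, max_lag)
}

# raw periodogram of a mean-subtracted series (positive frequencies)
.periodogram <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  f <- fft(xc)
  j <- seq_len(n %/% 2L)
  list(frequency = j / n, power = Mod(f[j + 1L])^2 / n, n = n)
}

#' Fourier power spectrum of a track
#'
#' Raw periodogram (no taper) of the mean-subtracted series.  Power at
#' frequency j/n is `|X_j|^2 / n`, so that summing power over all n Fourier
#' frequencies recovers `sum((x - mean(x))^2)` (Parseval).
#'
#' @param track A [position_track()] or numeric vector without missing values
#'   (trim or split around gaps first); length >= 64.
#' @return Object of class `"spectrum_result"`: list with `frequency`
#'   (cycles/bp), `power` and `n`.
#' @export
power_spectrum <- function(track) {
  x <- if (inherits(track, "position_track")) track$values else as.numeric(track)
  if (anyNA(x)) stop("track segment contains missing values; trim before the FFT")
  if (length(x) < 64L) stop("need at least 64 positions for a spectrum")
  structure(.periodogram(x), class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  imax <- which.max(x$power)
  cat(sprintf("<power spectrum> n = %d, dominant period %.2f bp\n",
              x$n, 1 / x$frequency[imax]))
  invisible(x)
}

#' Dominant period within a band
#'
#' @param spec A [power_spectrum()] result.
#' @param band Length-2 period interval in bp (inclusive).
#' @return The period (1/frequency) of maximal power inside the band.
#' @export
peak_period <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum_result"), length(band) == 2L)
  periods <- 1 / spec$frequency
  sel <- periods >= min(band) & periods <= max(band)
  if (!any(sel)) stop("no Fourier frequency falls inside the period band")
  periods[sel][which.max(spec$power[sel])]
}

# total periodogram power with period inside `band` (no length restriction;
# used on short profiles such as 50-bp frequency curves).  `snr = TRUE` also
# returns the band power relative to the median periodogram ordinate, a
# periodicity signal-to-noise measure.
.band_power <- function(x, band, snr = FALSE) {
  p <- .periodogram(x)
  periods <- 1 / p$frequency
  sel <- periods >= min(band) & periods <= max(band)
  if (!any(sel)) stop("no Fourier frequency falls inside the period band")
  bp <- sum(p$power[sel])
  if (!snr) return(bp)
  list(power = bp, snr = bp / (stats::median(p$power) * sum(sel)))
}

#' Mean track profile aligned at nucleosome dyads
#'
#' Averages the track over windows of `[-flank, +flank]` bp centered at each
#' dyad; dyads whose window leaves the track are skipped (and counted).
#'
#' @param track A [position_track()].
#' @param dyads Integer vector of 1-based dyad coordinates on the track's
#'   chromosome.
#' @param flank Flank size in bp (default 73, half a nucleosome).
#' @return `data.frame` with columns `offset` (-flank .. flank), `mean` and
#'   `n` (contributing dyads per offset); attribute `skipped` counts dyads
#'   lost to track edges.
#' @export
dyad_profile <- function(track, dyads, flank = 73L) {
  stopifnot(inherits(track, "position_track"), flank >= 1L)
  idx <- as.integer(dyads) - track$origin + 1L
  n <- length(track$values)
  usable <- idx - flank >= 1L & idx + flank <= n
  if (!any(usable)) stop("no dyad lies fully within the track after flanking")
  offs <- -flank:flank
  m <- outer(idx[usable], offs, `+`)
  vals <- matrix(track$values[m], nrow = sum(usable))
  cnt <- colSums(!is.na(vals))
  out <- data.frame(offset = offs, mean = colMeans(vals, na.rm = TRUE), n = cnt)
  out$mean[cnt == 0L] <- NA_real_
  attr(out, "skipped") <- sum(!usable)
  out
}

#' Tune the amplitude-ratio weight by A/T periodicity
#'
#' The historical procedure: for each candidate `f`, rank records by
#' `Q(f) = c26 + f * c31`, take the `top_n` highest, compute the per-position
#' A/T (W) frequency profile, and measure its Fourier power in the ~10-bp
#' period band.  Returns the `f` minimising that band power (smallest `f` on
#' ties).  If no grid value produces band power clearly above the
#' periodogram's noise floor there is no periodic signal to tune against and
#' the result carries `stable = FALSE`.
#'
#' @param library `data.frame` with columns `sequence`, `c26`, `c31` (a
#'   [sequence_set()] with those columns added works).
#' @param f_grid Candidate weights (> 0).
#' @param top_n Number of top-ranked records used (default 1000).
#' @param band Period band in bp (default `c(9, 12)`).
#' @param snr_min Minimum band-power-to-noise-floor ratio (at the worst grid
#'   value) for the tuning signal to be considered real.
#' @return List with `f` (best weight), `power` (`data.frame` of `f`,
#'   `band_power`, `snr`) and `stable` (logical).
#' @export
tune_amplitude_ratio <- function(library, f_grid, top_n = 1000L,
                                 band = c(9, 12), snr_min = 10) {
  stopifnot(all(c("sequence", "c26", "c31") %in% names(library)),
            length(f_grid) >= 1L, all(f_grid > 0))
  if (nrow(library) < top_n) stop("library smaller than `top_n`")
  f_grid <- sort(f_grid)
  m <- do.call(rbind, strsplit(toupper(library$sequence), "", fixed = TRUE))
  W <- m == "A" | m == "T"
  bp <- lapply(f_grid, function(f) {
    top <- order(q_score(library$c26, library$c31, f),
                 decreasing = TRUE, method = "radix")[seq_len(top_n)]
    .band_power(colMeans(W[top, , drop = FALSE]), band, snr = TRUE)
  })
  power <- vapply(bp, `[[`, numeric(1), "power")
  snr <- vapply(bp, `[[`, numeric(1), "snr")
  stable <- max(snr) >= snr_min
  if (!stable) {
    warning("no ~10-bp A/T periodicity above the noise floor at any f; ",
            "tuning result is unstable")
  }
  list(f = f_grid[which.min(power)],
       power = data.frame(f = f_grid, band_power = power, snr = snr),
       stable = stable)
}
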