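## Fractional-window moving-average smoothing.  At window size k the smoothed
## value at position l is
##   odd integer k:   plain mean of the k centered values;
##   even integer k:  endpoints at offsets +-k/2 weighted 1/(2k), the k-1
##                    interior offsets weighted 1/k (weights sum to 1);
##   fractional k:    (w1*S_k1 + w2*S_k2)/(w1+w2) with k1 < k < k2 the
##                    bracketing integers, w1 = 1/(k-k1), w2 = 1/(k2-k).
## At k equal to the helical repeat (10.4 bp) this kernel nearly annihilates
## the sinusoidal tether bias while preserving the slowly varying intrinsic
## signal.

#' Smoothing window descriptor
#'
#' @param k Window size in bp (> 1, possibly fractional).
#' @return List with `k`, bracketing integers `k1`, `k2` and weights
#'   `w1`, `w2` (`NULL` for integer `k`).
#' @export
smoothing_window <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 1) {
    stop("window size `k` must be a single number > 1")
  }
  if (k == round(k)) {
    list(k = k, k1 = as.integer(k), k2 = as.integer(k), w1 = NULL, w2 = NULL)
  } else {
    k1 <- floor(k); k2 <- ceiling(k)
    list(k = k, k1 = as.integer(k1), k2 = as.integer(k2),
         w1 = 1 / (k - k1), w2 = 1 / (k2 - k))
  }
}

# centered kernel weights for an integer window
.ma_kernel <- function(k) {
  if (k %% 2L == 1L) {
    rep(1 / k, k)
  } else {
    c(1 / (2 * k), rep(1 / k, k - 1L), 1 / (2 * k))
  }
}

.ma_integer <- function(x, k) {
  as.numeric(stats::filter(x, .ma_kernel(k), method = "convolution", sides = 2))
}

#' Fractional-window moving average
#'
#' Smooths a track with the moving-average kernel described above.  Positions
#' whose (widest) window is incomplete, or whose window contains a missing
#' value, are emitted as missing; output coordinates match the input.
#'
#' @param track A [position_track()] or plain numeric vector.
#' @param k Window size in bp (> 1; fractional values combine the two
#'   bracketing integer windows).
#' @return Smoothed track (or numeric vector, matching the input type).
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), k = 3)  # NA 2 3 4 NA
#' @export
moving_average <- function(track, k) {
  w <- smoothing_window(k)
  is_track <- inherits(track, "position_track")
  x <- if (is_track) track$values else as.numeric(track)
  if (all(is.na(x))) stop("cannot smooth an all-missing track")
  sm <- if (is.null(w$w1)) {
    .ma_integer(x, w$k1)
  } else {
    (w$w1 * .ma_integer(x, w$k1) + w$w2 * .ma_integer(x, w$k2)) / (w$w1 + w$w2)
  }
  if (is_track) position_track(sm, track$chrom, track$origin) else sm
}

#' Six-track smoothed estimate of intrinsic cyclizability
#'
#' The per-position mean of co-registered smoothed cyclizability tracks --
#' canonically the six k = 10.4 smoothed tracks for tether positions
#' n = 26, 29, 31 on the forward and reverse-complement strands.  A position
#' is missing whenever any constituent is missing.
#'
#' @param tracks List of >= 2 co-registered [position_track()] objects
#'   (six in the canonical estimator).
#' @return A [position_track()] of per-position means.
#' @export
c0s_estimate <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2L) {
    stop("`tracks` must be a list of at least two position tracks")
  }
  ref <- .check_coregistered(tracks)
  m <- vapply(tracks, function(t) t$values, numeric(length(ref$values)))
  position_track(rowMeans(m), ref$chrom, ref$origin)
}

#' Window-size consistency scan
#'
#' For each candidate window size, smooths every track and reports the mean
#' pairwise Pearson correlation among the smoothed tracks over jointly
#' non-missing positions.  Consistency across tether positions peaks when the
#' window matches the helical repeat.
#'
#' @param tracks List of >= 2 co-registered [position_track()] objects (one
#'   per tether position).
#' @param k_values Numeric vector of window sizes (> 1; `k = 1` is accepted
#'   as "no smoothing").
#' @return `data.frame` with columns `k` and `mean_cor`.
#' @export
window_consistency_scan <- function(tracks, k_values) {
  if (!is.list(tracks) || length(tracks) < 2L) stop("need at least two tracks")
  .check_coregistered(tracks)
  if (any(k_values < 1)) stop("window sizes must be >= 1")
  mean_cor <- vapply(k_values, function(k) {
    sm <- lapply(tracks, function(t) {
      if (k == 1) t$values else moving_average(t$values, k)
    })
    m <- do.call(cbind, sm)
    ok <- complete.cases(m)
    cm <- cor(m[ok, , drop = FALSE])
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  data.frame(k = k_values, mean_cor = mean_cor)
}

#' Local amplitude by half-range
#'
#' Approximates the local sinusoid amplitude at position l as half the range
#' of track values over `[l - halfwidth, l + halfwidth]` (with the default
#' halfwidth of 5 bp the window spans roughly one helical turn).  Edges are
#' missing.
#'
#' @param track A [position_track()] or numeric vector.
#' @param halfwidth Integer half-window in bp (>= 1, default 5).
#' @return Amplitude track (or numeric vector, matching the input type).
#' @export
local_amplitude <- function(track, halfwidth = 5L) {
  if (halfwidth < 1L || halfwidth != round(halfwidth)) {
    stop("`halfwidth` must be a positive integer")
  }
  is_track <- inherits(track, "position_track")
  x <- if (is_track) track$values else as.numeric(track)
  w <- 2L * halfwidth + 1L
  if (length(x) < w) stop("track shorter than the amplitude window")
  m <- as.data.frame(embed(x, w))
  hi <- do.call(pmax, m)
  lo <- do.call(pmin, m)
  amp <- c(rep(NA_real_, halfwidth), (hi - lo) / 2, rep(NA_real_, halfwidth))
  if (is_track) position_track(amp, track$chrom, track$origin) else amp
}

#' Per-position amplitude ratio of two amplitude tracks
#'
#' @param amp_a,amp_b Co-registered amplitude tracks ([position_track()]).
#' @param tol Denominator magnitudes below `tol` give missing output.
#' @return Track of `amp_a / amp_b`.
#' @export
amplitude_ratio_track <- function(amp_a, amp_b, tol = 1e-8) {
  ref <- .check_coregistered(list(amp_a, amp_b))
  den <- amp_b$values
  out <- amp_a$values / den
  out[!is.na(den) & abs(den) < tol] <- NA_real_
  position_track(out, ref$chrom, ref$origin)
}
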