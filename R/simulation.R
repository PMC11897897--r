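## Simulation benchmark of the intrinsic-cyclizability estimators.  Observed
## tracks follow the forward tether-bias model
##   C_n(l) = C_0(l) + A_n(l) sin(2 pi n / 10.4 + phi(l)) + eps_n(l)
## with C_0 and A_26 bounded random walks, phase decrementing 2 pi / 10.4 per
## bp from a uniform start, and three amplitude-ratio regimes:
##   (i)   A_31 = A_26/0.7,  A_29 = A_26/0.82   (solver ratios are the truth)
##   (ii)  A_31 = 0.7 A_26,  A_29 = 0.82 A_26   (inverted truth)
##   (iii) A_31 = a A_26,    A_29 = b A_26 with log(a), log(b) independent
##         bounded walks (a, b in [0.2, 1.5]).

#' Bounded random walk with opposite-step reflection
#'
#' Each step is Normal(0, `step_sd`^2); a step that would leave
#' `[lower, upper]` is instead taken in the opposite direction with the same
#' magnitude (and clamped to the bound in the rare case it is still outside).
#'
#' @param length Number of values to generate (>= 1).
#' @param step_sd Step standard deviation (>= 0).
#' @param lower,upper Bounds (`lower <= upper`; equal bounds give a constant
#'   series).
#' @param init Start value, or `NULL` for uniform in the bounds (the walk's
#'   stationary regime).
#' @return Numeric vector of `length` values, all within the bounds.
#' @export
bounded_random_walk <- function(length, step_sd, lower, upper, init = NULL) {
  stopifnot(length >= 1, step_sd >= 0, lower <= upper)
  if ((upper - lower) < 4 * step_sd) {
    warning("bounds narrower than 4 * step_sd; opposite-step reflection degrades")
  }
  x <- numeric(length)
  x[1] <- if (is.null(init)) runif(1, lower, upper) else init
  if (x[1] < lower || x[1] > upper) stop("`init` outside bounds")
  if (length == 1L) return(x)
  steps <- rnorm(length - 1L, 0, step_sd)
  for (i in 2:length) {
    cand <- x[i - 1L] + steps[i - 1L]
    if (cand < lower || cand > upper) cand <- x[i - 1L] - steps[i - 1L]
    x[i] <- min(max(cand, lower), upper)
  }
  x
}

#' Simulation setting for the estimator benchmark
#'
#' Defaults are the benchmark's stated generative world: 100 000 positions;
#' intrinsic-cyclizability walk with step sd 1/12 in \[-2, 2\]; amplitude walk
#' with step sd 1/5 in \[0.1, 3\]; log-ratio walks (setting iii) with step sd
#' 1/10 and ratios in \[0.2, 1.5\]; observation noise sd 1/4.
#'
#' @param label `"i"`, `"ii"` or `"iii"` (amplitude-ratio regime, see above).
#' @param length Number of chromosome positions.
#' @param noise_sd Observation noise standard deviation.
#' @param seed Integer master seed; component sub-streams (each walk, the
#'   phase start, each noise track) are derived from it so that overriding
#'   one parameter perturbs only its component.
#' @param period Helical repeat in bp.
#' @param c0_walk,a26_walk,ratio_walk Lists `list(step_sd, lower, upper)`
#'   describing the bounded walks (`ratio_walk` bounds are on the ratio value
#'   scale; the walk itself lives on the log scale).
#' @param shared_noise If `TRUE`, one noise draw per position is shared by the
#'   three tether positions instead of independent draws per (n, l).  The
#'   independent default is the documented modelling choice: shared noise
#'   would survive both smoothing and averaging.
#' @return An object of class `"simulation_setting"`.
#' @export
simulation_setting <- function(label = c("i", "ii", "iii"),
                               length = 100000L,
                               noise_sd = 0.25,
                               seed = 1L,
                               period = 10.4,
                               c0_walk = list(step_sd = 1 / 12, lower = -2, upper = 2),
                               a26_walk = list(step_sd = 1 / 5, lower = 0.1, upper = 3),
                               ratio_walk = list(step_sd = 1 / 10, lower = 0.2, upper = 1.5),
                               shared_noise = FALSE) {
  label <- match.arg(label)
  stopifnot(length >= 100, noise_sd >= 0, period > 0)
  structure(list(label = label, length = as.integer(length),
                 noise_sd = noise_sd, seed = as.integer(seed), period = period,
                 c0_walk = c0_walk, a26_walk = a26_walk, ratio_walk = ratio_walk,
                 shared_noise = isTRUE(shared_noise)),
            class = "simulation_setting")
}

# draw substream seeds deterministically from a master seed
.substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

#' Run one simulation setting
#'
#' Generates the ground-truth tracks (`c0`, `a26`, `a29`, `a31`, `phi`) and
#' the observed tracks (`c26`, `c29`, `c31`) under the forward model.
#'
#' @param setting A [simulation_setting()].
#' @return A `"simulation_result"` list with elements `setting`, `truth`
#'   (list of numeric vectors) and `observed` (list of numeric vectors).
#' @export
simulate_setting <- function(setting) {
  stopifnot(inherits(setting, "simulation_setting"))
  L <- setting$length
  ss <- .substream_seeds(setting$seed, 8L)
  cw <- setting$c0_walk; aw <- setting$a26_walk; rw <- setting$ratio_walk
  c0  <- .with_seed(ss[1], bounded_random_walk(L, cw$step_sd, cw$lower, cw$upper))
  a26 <- .with_seed(ss[2], bounded_random_walk(L, aw$step_sd, aw$lower, aw$upper))
  if (setting$label == "i") {
    a31 <- a26 / 0.7
    a29 <- a26 / 0.82
  } else if (setting$label == "ii") {
    a31 <- 0.7 * a26
    a29 <- 0.82 * a26
  } else {
    la <- .with_seed(ss[3], bounded_random_walk(L, rw$step_sd, log(rw$lower), log(rw$upper)))
    lb <- .with_seed(ss[4], bounded_random_walk(L, rw$step_sd, log(rw$lower), log(rw$upper)))
    a31 <- exp(la) * a26
    a29 <- exp(lb) * a26
  }
  phi0 <- .with_seed(ss[5], runif(1, 0, 2 * pi))
  phi <- phi0 - 2 * pi * (seq_len(L) - 1) / setting$period
  eps <- function(s) .with_seed(s, rnorm(L, 0, setting$noise_sd))
  if (setting$shared_noise) {
    e <- eps(ss[6]); e26 <- e29 <- e31 <- e
  } else {
    e26 <- eps(ss[6]); e29 <- eps(ss[7]); e31 <- eps(ss[8])
  }
  cn <- function(n, an, e) c0 + an * sin(2 * pi * n / setting$period + phi) + e
  structure(list(
    setting = setting,
    truth = list(c0 = c0, a26 = a26, a29 = a29, a31 = a31, phi = phi),
    observed = list(c26 = cn(26, a26, e26), c29 = cn(29, a29, e29),
                    c31 = cn(31, a31, e31))),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation result> setting (%s), %d positions, seed %d\n",
              x$setting$label, x$setting$length, x$setting$seed))
  invisible(x)
}

.cor_safe <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop("degenerate (constant) track in correlation")
  cor(x[ok], y[ok])
}

#' Correlation summary of the estimators against the truth
#'
#' Computes, against the true intrinsic cyclizability: the raw observed
#' tracks; each track smoothed at window `k`; the mean of the three smoothed
#' tracks; and the per-position closed-form solution under the assumed
#' amplitude-ratio scheme.
#'
#' @param result A [simulate_setting()] result.
#' @param k Smoothing window size (default 10.4, the helical repeat).
#' @param scheme Assumed [amplitude_ratio_scheme()] for the per-position solve.
#' @return `data.frame` with columns `estimator` and `r` (eight rows:
#'   `c26`, `c29`, `c31`, `c26_s`, `c29_s`, `c31_s`, `cbar`, `c0hat`).
#' @export
evaluate_correlations <- function(result, k = 10.4,
                                  scheme = amplitude_ratio_scheme(0.7)) {
  stopifnot(inherits(result, "simulation_result"))
  obs <- result$observed
  c0 <- result$truth$c0
  sm <- lapply(obs, moving_average, k = k)
  cbar <- (sm$c26 + sm$c29 + sm$c31) / 3
  c0hat <- solve_c0_table(obs$c26, obs$c29, obs$c31, scheme)$c0
  data.frame(
    estimator = c("c26", "c29", "c31", "c26_s", "c29_s", "c31_s", "cbar", "c0hat"),
    r = c(.cor_safe(obs$c26, c0), .cor_safe(obs$c29, c0), .cor_safe(obs$c31, c0),
          .cor_safe(sm$c26, c0), .cor_safe(sm$c29, c0), .cor_safe(sm$c31, c0),
          .cor_safe(cbar, c0), .cor_safe(c0hat, c0)))
}

#' Ratio-misspecification heatmap
#'
#' Correlation between the per-position closed-form solution and the true
#' intrinsic cyclizability over a grid of assumed amplitude ratios.  The
#' assumed `A26/A29` enters the solver directly, overriding the interpolation
#' rule.  Grid cells whose system is (near-)singular are returned as `NA`.
#'
#' @param x A [simulation_setting()] (simulated on the fly) or an existing
#'   [simulate_setting()] result.
#' @param ratio31_grid,ratio29_grid Assumed `A26/A31` and `A26/A29` values
#'   (positive; default 21 evenly spaced values in \[0.5, 1.5\]).
#' @return Numeric matrix of correlations, rows indexed by `A26/A31`, columns
#'   by `A26/A29`.
#' @export
ratio_heatmap <- function(x,
                          ratio31_grid = seq(0.5, 1.5, length.out = 21),
                          ratio29_grid = seq(0.5, 1.5, length.out = 21)) {
  result <- if (inherits(x, "simulation_setting")) simulate_setting(x) else x
  stopifnot(inherits(result, "simulation_result"))
  if (any(ratio31_grid <= 0) || any(ratio29_grid <= 0)) {
    stop("grid ratios must be positive")
  }
  obs <- result$observed
  c0 <- result$truth$c0
  obs_mat <- rbind(obs$c26, obs$c29, obs$c31)
  sch <- amplitude_ratio_scheme(1, period = result$setting$period)
  out <- matrix(NA_real_, length(ratio31_grid), length(ratio29_grid),
                dimnames = list(ratio31 = sprintf("%.3f", ratio31_grid),
                                ratio29 = sprintf("%.3f", ratio29_grid)))
  for (i in seq_along(ratio31_grid)) {
    for (j in seq_along(ratio29_grid)) {
      w <- tryCatch(
        .solver_matrix(sch, r_override = c(1, ratio29_grid[j], ratio31_grid[i]))[1, ],
        error = function(e) NULL)
      if (is.null(w)) next
      out[i, j] <- .cor_safe(drop(w %*% obs_mat), c0)
    }
  }
  out
}

#' Sensitivity analysis of the averaged smoothed estimator
#'
#' Re-runs a base setting with the walk/noise variances scaled and reports
#' the correlation between the mean smoothed track and the truth.  Variance
#' multipliers scale the corresponding standard deviations by their square
#' root; the master seed is reused so each override perturbs only the
#' magnitude of its component.
#'
#' @param base A [simulation_setting()].
#' @param overrides `data.frame` with any of the columns `c0_var`, `a26_var`,
#'   `ratio_var`, `noise_var` (variance multipliers > 0, default 1), one row
#'   per run.
#' @param k Smoothing window size.
#' @return `overrides` with an appended column `r_cbar`.
#' @export
sensitivity_run <- function(base, overrides, k = 10.4) {
  stopifnot(inherits(base, "simulation_setting"), is.data.frame(overrides))
  get_mult <- function(row, name) {
    m <- if (name %in% names(overrides)) overrides[[name]][row] else 1
    if (!is.finite(m) || m <= 0) stop("variance multipliers must be > 0")
    m
  }
  r_cbar <- vapply(seq_len(nrow(overrides)), function(i) {
    s <- base
    s$c0_walk$step_sd <- s$c0_walk$step_sd * sqrt(get_mult(i, "c0_var"))
    s$a26_walk$step_sd <- s$a26_walk$step_sd * sqrt(get_mult(i, "a26_var"))
    s$ratio_walk$step_sd <- s$ratio_walk$step_sd * sqrt(get_mult(i, "ratio_var"))
    s$noise_sd <- s$noise_sd * sqrt(get_mult(i, "noise_var"))
    res <- simulate_setting(s)
    ev <- evaluate_correlations(res, k = k)
    ev$r[ev$estimator == "cbar"]
  }, numeric(1))
  cbind(overrides, r_cbar = r_cbar)
}
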