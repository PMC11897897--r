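## Sinusoidal biotin-tether bias model and the closed-form intrinsic-
## cyclizability solver.  A measured cyclizability with the tether at
## position n decomposes as
##     C_n = C_0 + A_n * sin(2*pi*n/period + phi0),
## with period the DNA helical repeat (default 10.4 bp).  With only three
## observations (n = 26, 29, 31) per sequence the amplitudes A_n are not
## identifiable; an amplitude-ratio scheme pins them to A_26 via an assumed
## A_26/A_31 ratio and linear interpolation in n, after which (C_0, A_26,
## phi0) solve a 3x3 linear system exactly.

.check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Amplitude-ratio scheme for the tether-bias model
#'
#' Encodes the assumed ratio \eqn{A_{26}/A_{31}} together with the linear
#' interpolation rule in the tether position \eqn{n}:
#' \eqn{r_n = A_{26}/A_n = 1 - (n - 26)(1 - r_{31})/5}, so that
#' \eqn{r_{26} = 1} exactly and the default `ratio31 = 0.7` yields
#' \eqn{r_{29} = 0.82}.
#'
#' @param ratio31 Assumed \eqn{A_{26}/A_{31}} ratio (> 0, default 0.7).
#' @param period DNA helical repeat in bp (> 0, default 10.4).
#' @return An object of class `"amp_ratio_scheme"`.
#' @examples
#' sch <- amplitude_ratio_scheme(0.7)
#' ratio_at(sch, c(26, 29, 31))  # 1.00 0.82 0.70
#' @export
amplitude_ratio_scheme <- function(ratio31 = 0.7, period = 10.4) {
  .check_finite(ratio31, "ratio31")
  .check_finite(period, "period")
  if (length(ratio31) != 1L || ratio31 <= 0) stop("`ratio31` must be a single positive number")
  if (length(period) != 1L || period <= 0) stop("`period` must be a single positive number")
  structure(list(ratio31 = ratio31, period = period),
            class = "amp_ratio_scheme")
}

#' @rdname amplitude_ratio_scheme
#' @param scheme An `amp_ratio_scheme`.
#' @param n Tether position(s) in bp.
#' @export
ratio_at <- function(scheme, n) {
  stopifnot(inherits(scheme, "amp_ratio_scheme"))
  r <- 1 - (n - 26) * (1 - scheme$ratio31) / 5
  if (any(r <= 0)) {
    stop(sprintf("scheme ratio31=%g gives non-positive amplitude ratio at n = %s",
                 scheme$ratio31, paste(n[r <= 0], collapse = ", ")))
  }
  r
}

#' @export
print.amp_ratio_scheme <- function(x, ...) {
  cat(sprintf("<amplitude ratio scheme> A26/A31 = %g (A26/A29 = %g), period = %g bp\n",
              x$ratio31, ratio_at(x, 29), x$period))
  invisible(x)
}

#' Tether-bias term of the cyclizability model
#'
#' The additive bias contributed by the biotin tether at position `n`:
#' `amplitude * sin(2*pi*n/period + phi0)`.
#'
#' @param n Tether position in bp.
#' @param phi0 Phase in radians.
#' @param amplitude Bias amplitude (>= 0).
#' @param period Helical repeat in bp (default 10.4).
#' @return Numeric bias value(s).
#' @examples
#' bias_term(26, 0, 1)  # ~0: 26 bp is 2.5 exact helical turns at period 10.4
#' @export
bias_term <- function(n, phi0, amplitude, period = 10.4) {
  .check_finite(n, "n"); .check_finite(phi0, "phi0")
  .check_finite(amplitude, "amplitude"); .check_finite(period, "period")
  if (any(amplitude < 0)) stop("`amplitude` must be >= 0")
  amplitude * sin(2 * pi * n / period + phi0)
}

#' Forward evaluation of the tether-bias model
#'
#' Computes `c0 + (a26 / r_n) * sin(2*pi*n/period + phi0)` where `r_n` is the
#' scheme's amplitude ratio at `n`.
#'
#' @param c0 Intrinsic cyclizability.
#' @param a26 Amplitude at tether position 26 (>= 0).
#' @param phi0 Phase in radians.
#' @param n Tether position(s).
#' @param scheme An [amplitude_ratio_scheme()].
#' @return Predicted cyclizability value(s).
#' @export
forward_cn <- function(c0, a26, phi0, n, scheme = amplitude_ratio_scheme()) {
  .check_finite(c0, "c0"); .check_finite(a26, "a26"); .check_finite(phi0, "phi0")
  if (any(a26 < 0)) stop("`a26` must be >= 0")
  r <- ratio_at(scheme, n)
  c0 + (a26 / r) * sin(2 * pi * n / scheme$period + phi0)
}

# Design matrix of the linearized system C_n = c0 + (1/r_n) (u sin th + v cos th)
# with u = a26 cos(phi0), v = a26 sin(phi0).  `r_override` replaces the
# interpolated ratios (used by the heatmap's direct A26/A29 grid).
.design_matrix <- function(scheme, ns = c(26, 29, 31), r_override = NULL) {
  theta <- 2 * pi * ns / scheme$period
  r <- if (is.null(r_override)) ratio_at(scheme, ns) else r_override
  cbind(intercept = 1, u = sin(theta) / r, v = cos(theta) / r)
}

# Inverse of the design matrix; errors on near-singular schemes.
.solver_matrix <- function(scheme, ns = c(26, 29, 31), r_override = NULL,
                           rcond_tol = 1e-10) {
  M <- .design_matrix(scheme, ns, r_override)
  if (rcond(M) < rcond_tol) {
    stop(sprintf(
      "amplitude-ratio scheme (ratio31=%g, period=%g) yields a (near-)singular system",
      scheme$ratio31, scheme$period))
  }
  solve(M)
}

.wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

#' Solve the tether-bias model for one observation triplet
#'
#' Inverts the three-equation system `C_n = c0 + (a26/r_n) sin(2 pi n/period
#' + phi0)` at `n = 26, 29, 31` exactly via the linearizing substitution
#' `u = a26 cos(phi0)`, `v = a26 sin(phi0)`.
#'
#' @param obs Numeric length-3 vector `(c26, c29, c31)`, or a list/data.frame
#'   row with elements `c26`, `c29`, `c31`.
#' @param scheme An [amplitude_ratio_scheme()].
#' @param amp_tol Amplitudes below this leave the phase flagged undefined
#'   (`phi0 = NA`).
#' @return A `"biotin_fit"` list with elements `c0`, `a26`, `phi0` (radians in
#'   `[-pi, pi)`, `NA` when the amplitude is degenerate), and `scheme`.
#' @examples
#' fit <- solve_c0(c(1.18, -0.36, -3.17), amplitude_ratio_scheme(0.7))
#' round(fit$c0, 2)  # -0.67
#' @export
solve_c0 <- function(obs, scheme = amplitude_ratio_scheme(), amp_tol = 1e-12) {
  if (is.list(obs)) obs <- c(obs$c26, obs$c29, obs$c31)
  .check_finite(obs, "obs")
  if (length(obs) != 3L) stop("`obs` must supply exactly (c26, c29, c31)")
  sol <- drop(.solver_matrix(scheme) %*% obs)
  a26 <- sqrt(sol[2]^2 + sol[3]^2)
  phi0 <- if (a26 < amp_tol) NA_real_ else .wrap_phase(atan2(sol[3], sol[2]))
  structure(list(c0 = unname(sol[1]), a26 = unname(a26), phi0 = unname(phi0),
                 scheme = scheme),
            class = "biotin_fit")
}

#' @export
print.biotin_fit <- function(x, ...) {
  cat(sprintf("<biotin fit> c0 = %.4f, a26 = %.4f, phi0 = %s rad (A26/A31 = %g)\n",
              x$c0, x$a26,
              if (is.na(x$phi0)) "undefined" else sprintf("%.4f", x$phi0),
              x$scheme$ratio31))
  invisible(x)
}

#' @export
predict.biotin_fit <- function(object, n = c(26, 29, 31), ...) {
  phi <- if (is.na(object$phi0)) 0 else object$phi0
  forward_cn(object$c0, object$a26, phi, n, object$scheme)
}

#' Vectorised per-observation solve
#'
#' Applies [solve_c0()] to many `(c26, c29, c31)` triplets at once (the
#' system matrix depends only on the scheme, so this is a single matrix
#' product).
#'
#' @param c26,c29,c31 Equal-length numeric vectors.
#' @inheritParams solve_c0
#' @param r_override Optional length-3 vector of amplitude ratios
#'   `(r26, r29, r31)` replacing the scheme's interpolation rule.
#' @return `data.frame` with columns `c0`, `a26`, `phi0`.
#' @export
solve_c0_table <- function(c26, c29, c31, scheme = amplitude_ratio_scheme(),
                           r_override = NULL, amp_tol = 1e-12) {
  stopifnot(length(c26) == length(c29), length(c26) == length(c31))
  Minv <- .solver_matrix(scheme, r_override = r_override)
  sol <- Minv %*% rbind(c26, c29, c31)
  a26 <- sqrt(sol[2, ]^2 + sol[3, ]^2)
  phi0 <- .wrap_phase(atan2(sol[3, ], sol[2, ]))
  phi0[a26 < amp_tol] <- NA_real_
  data.frame(c0 = sol[1, ], a26 = a26, phi0 = phi0)
}

#' Two-point antiphase approximation of intrinsic cyclizability
#'
#' Because the tether bias at n = 26 and n = 31 is nearly antiphase
#' (5 bp is close to half a helical turn), `(c26/f + c31)/(1 + 1/f)` with
#' `f = A26/A31` approximately cancels the bias.
#'
#' @param c26,c31 Cyclizability observations (vectors allowed).
#' @param f Assumed amplitude ratio weight (> 0, default 0.7).
#' @return Approximate intrinsic cyclizability.
#' @export
approx_c0 <- function(c26, c31, f = 0.7) {
  .check_finite(c26, "c26"); .check_finite(c31, "c31"); .check_finite(f, "f")
  if (any(f <= 0)) stop("`f` must be > 0")
  (c26 / f + c31) / (1 + 1 / f)
}

#' Historical Q(f) ranking score
#'
#' `c26 + f * c31`, the combination historically used to tune the assumed
#' amplitude ratio by minimising ~10-bp A/T periodicity among top-ranked
#' sequences (see [tune_amplitude_ratio()]).
#'
#' @inheritParams approx_c0
#' @return Numeric score(s).
#' @export
q_score <- function(c26, c31, f) {
  .check_finite(c26, "c26"); .check_finite(c31, "c31"); .check_finite(f, "f")
  c26 + f * c31
}

#' Phase progression along a chromosome
#'
#' Moving the 50-bp window k bp downstream advances the DNA helix k bp, so the
#' tether phase decrements by `2*pi*k/period`: returns
#' `phi - 2*pi*k/period` wrapped to `[-pi, pi)`.
#'
#' @param phi Phase in radians.
#' @param k Offset in bp (may be fractional).
#' @param period Helical repeat in bp.
#' @return Wrapped phase in radians.
#' @export
phase_progress <- function(phi, k, period = 10.4) {
  .check_finite(phi, "phi"); .check_finite(k, "k"); .check_finite(period, "period")
  .wrap_phase(phi - 2 * pi * k / period)
}
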