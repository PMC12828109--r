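## Decision thresholds for the sequential test.  Wald's classical thresholds
## ln((1-beta)/alpha) and ln((1-alpha)/beta) ignore the overshoot of the
## log-likelihood-ratio statistic at its first boundary crossing and are
## therefore conservative.  Nonlinear renewal theory corrects them with the
## Laplace transforms gamma0, gamma1 of the limiting overshoot distributions,
## giving strictly narrower thresholds a = ln((1-beta) gamma1 / alpha),
## b = ln((1-alpha) gamma0 / beta).

# Fitted trigonometric approximation gamma_j = a1 * sin(a2 * delta_star) + a3,
# one row per (delta_star range, hypothesis).  The two fitted ranges are
# [0.2, 0.8] (event-rate shortfall designs) and [1.2, 2.0] (safety designs);
# the gap around 1 is not covered because the test degenerates as
# delta_star -> 1.
.gamma_coef <- data.frame(
  range_low  = c(0.2,   0.2,   1.2,    1.2),
  range_high = c(0.8,   0.8,   2.0,    2.0),
  hypothesis = c("null", "alternative", "null", "alternative"),
  a1 = c(0.582, 0.888, -1.648, -0.534),
  a2 = c(1.606, 1.297,  0.750,  0.616),
  a3 = c(0.364, 0.078,  1.993,  1.300),
  stringsAsFactors = FALSE)

#' Fitted trigonometric coefficients for the overshoot corrections
#'
#' Returns the coefficient table of the sine approximation
#' `gamma_j = a1 * sin(a2 * delta_star) + a3` to the Laplace transform of the
#' limiting boundary-overshoot distribution, fitted separately for the null
#' (`gamma0`, lower boundary) and alternative (`gamma1`, upper boundary)
#' hypotheses on the two supported `delta_star` ranges.
#'
#' @return A data frame with columns `range_low`, `range_high`, `hypothesis`,
#'   `a1`, `a2`, `a3`.
#' @seealso [gamma_approx()], [fit_trig()]
#' @export
gamma_coefficients <- function() .gamma_coef

#' Overshoot correction factor from the fitted sine approximation
#'
#' Evaluates `gamma0` (hypothesis `"null"`, used for the lower threshold) or
#' `gamma1` (hypothesis `"alternative"`, upper threshold) at a given effective
#' ratio `delta_star`.  The sine argument is in radians.  Outside the fitted
#' ranges `[0.2, 0.8]` and `[1.2, 2.0]` no extrapolation is attempted; use the
#' calibration module ([simulate_gamma()]) for such designs.
#'
#' @param delta_star Effective hazard ratio, see [effective_ratio()].
#' @param hypothesis `"null"` for `gamma0` or `"alternative"` for `gamma1`.
#' @return The correction factor, a value in (0, 1).
#' @examples
#' gamma_approx(0.734, "null")          # gamma0
#' gamma_approx(0.734, "alternative")   # gamma1
#' @export
gamma_approx <- function(delta_star, hypothesis = c("null", "alternative")) {
  hypothesis <- match.arg(hypothesis)
  if (!is.numeric(delta_star) || length(delta_star) != 1L || is.na(delta_star))
    stop("`delta_star` must be a single number", call. = FALSE)
  tab <- .gamma_coef[.gamma_coef$hypothesis == hypothesis, ]
  row <- tab[delta_star >= tab$range_low & delta_star <= tab$range_high, ]
  if (nrow(row) != 1L)
    stop(sprintf(paste0(
      "delta_star = %.4g is outside the fitted ranges [0.2, 0.8] and ",
      "[1.2, 2.0]; no sine approximation is available there. ",
      "Estimate gamma by overshoot simulation with simulate_gamma()."),
      delta_star), call. = FALSE)
  row$a1 * sin(row$a2 * delta_star) + row$a3
}

#' Sequential decision thresholds from error rates and overshoot corrections
#'
#' Computes the upper threshold `a = log((1 - beta) * gamma1 / alpha)` and the
#' magnitude `b = log((1 - alpha) * gamma0 / beta)` of the lower threshold
#' `-b`.  With `gamma0 = gamma1 = 1` these reduce to Wald's thresholds; for
#' any `gamma < 1` they are strictly narrower.
#'
#' @param alpha,beta Nominal type I and type II error rates, in (0, 1).
#' @param gamma0,gamma1 Overshoot correction factors in (0, 1\]; defaults of 1
#'   give Wald's thresholds.
#' @return An object of class `serm_boundaries` with fields `a`, `b`,
#'   `gamma0`, `gamma1`, `alpha`, `beta`.
#' @examples
#' boundary_pair(0.05, 0.10, gamma0 = 0.902, gamma1 = 0.801)
#' @export
boundary_pair <- function(alpha, beta, gamma0 = 1, gamma1 = 1) {
  .check_prob(alpha, "alpha")
  .check_prob(beta, "beta")
  for (g in c(gamma0 = gamma0, gamma1 = gamma1))
    if (!is.numeric(g) || g <= 0 || g > 1)
      stop("gamma values must lie in (0, 1]", call. = FALSE)
  a <- log((1 - beta) * gamma1 / alpha)
  b <- log((1 - alpha) * gamma0 / beta)
  if (a <= 0 || b <= 0)
    stop(sprintf(paste0(
      "degenerate boundaries (a = %.4g, b = %.4g): the error rates are too ",
      "large for the requested gamma corrections"), a, b), call. = FALSE)
  structure(list(a = a, b = b, gamma0 = gamma0, gamma1 = gamma1,
                 alpha = alpha, beta = beta),
            class = "serm_boundaries")
}

#' Wald's uncorrected sequential thresholds
#'
#' The classical SPRT thresholds `a = log((1 - beta)/alpha)`,
#' `b = log((1 - alpha)/beta)`, provided as a comparison baseline for the
#' overshoot-corrected pair.
#'
#' @inheritParams boundary_pair
#' @return A `serm_boundaries` object with `gamma0 = gamma1 = 1`.
#' @export
wald_boundaries <- function(alpha, beta) boundary_pair(alpha, beta, 1, 1)

#' Decision thresholds for a monitoring design
#'
#' Convenience wrapper: derives `delta_star` from the design, evaluates the
#' sine approximations for `gamma0` and `gamma1` (unless explicit values are
#' supplied, e.g. from [simulate_gamma()]), and returns the threshold pair.
#'
#' @param design A `serm_design` or `serm_derived` object.
#' @param gamma0,gamma1 Optional overrides for the correction factors.
#' @return A `serm_boundaries` object.
#' @examples
#' d <- serm_design(p0 = 0.15, n0 = 4600, T0 = 1095, Tf = 730)
#' serm_boundaries(d)
#' @export
serm_boundaries <- function(design, gamma0 = NULL, gamma1 = NULL) {
  dd <- derive_design(design)
  if (is.null(gamma0)) gamma0 <- gamma_approx(dd$delta_star, "null")
  if (is.null(gamma1)) gamma1 <- gamma_approx(dd$delta_star, "alternative")
  boundary_pair(dd$design$alpha, dd$design$beta, gamma0 = gamma0,
                gamma1 = gamma1)
}

#' @export
print.serm_boundaries <- function(x, ...) {
  w <- wald_boundaries(x$alpha, x$beta)
  cat(sprintf("SPRT thresholds (alpha = %.3g, beta = %.3g)\n", x$alpha, x$beta))
  cat(sprintf("  upper a = %.4f, lower -b = %.4f  (gamma1 = %.4f, gamma0 = %.4f)\n",
              x$a, -x$b, x$gamma1, x$gamma0))
  cat(sprintf("  Wald baseline: a = %.4f, -b = %.4f\n", w$a, -w$b))
  invisible(x)
}
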