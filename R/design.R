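## Trial design and the reduction of the event-proportion hypotheses to an
## SPRT on a unit exponential hazard.  All user-facing times are in days;
## the monitor works on dimensionless rescaled times (multiplied by theta0).

.stop_invalid <- function(param, msg) {
  stop(sprintf("invalid design: `%s` %s", param, msg), call. = FALSE)
}

.check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stop_invalid(name, "must be a single number")
  if (open && (x <= 0 || x >= 1)) .stop_invalid(name, "must lie in (0, 1)")
  if (!open && (x < 0 || x >= 1)) .stop_invalid(name, "must lie in [0, 1)")
  invisible(x)
}

#' Effective hazard ratio implied by an event-proportion ratio
#'
#' Converts the pair (planned event proportion `p0`, design ratio `delta`) into
#' the ratio of exponential hazards `delta_star` that the sequential statistic
#' actually tests.  Testing `p = p0` against `p = delta * p0` for the
#' proportion of events by the average follow-up time is equivalent, for
#' exponential lifetimes, to testing a unit hazard against hazard
#' `delta_star = log(1 - delta * p0) / log(1 - p0)`.
#'
#' `delta < 1` monitors for an event-rate shortfall; `delta > 1` (e.g. safety
#' monitoring of an adverse-event rate) is equally valid and yields
#' `delta_star > 1`.
#'
#' @param p0 Planned event proportion by the average follow-up, in (0, 1).
#' @param delta Design ratio (> 0) with `delta * p0 < 1`.
#' @return The dimensionless effective ratio `delta_star`; strictly increasing
#'   in `delta`, equal to 1 iff `delta == 1`, and tending to `delta` as
#'   `p0 -> 0`.
#' @examples
#' effective_ratio(0.15, 0.75)   # 0.734
#' @export
effective_ratio <- function(p0, delta) {
  .check_prob(p0, "p0")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    .stop_invalid("delta", "must be a positive number")
  if (delta * p0 >= 1)
    .stop_invalid("delta", sprintf(
      "gives delta * p0 = %.4g >= 1; the alternative proportion is not a probability",
      delta * p0))
  log1p(-delta * p0) / log1p(-p0)
}

#' Exponential hazard matching an event proportion
#'
#' Returns the hazard rate `theta = -log(1 - p) / Ta` such that an exponential
#' lifetime with this rate has probability exactly `p` of an event by time
#' `Ta`.
#'
#' @param p Event proportion in \[0, 1).
#' @param Ta Reference follow-up duration (days, > 0), typically the average
#'   follow-up time of the trial.
#' @return Hazard rate per day.
#' @examples
#' hazard_from_proportion(0.15, 1277.5)
#' @export
hazard_from_proportion <- function(p, Ta) {
  .check_prob(p, "p", open = FALSE)
  if (!is.numeric(Ta) || length(Ta) != 1L || is.na(Ta) || Ta <= 0)
    .stop_invalid("Ta", "must be a positive duration")
  -log1p(-p) / Ta
}

#' Specify a trial design for sequential event-rate monitoring
#'
#' Collects the user-facing design parameters of the trial.  `derive_design()`
#' turns these into the transformed quantities the monitor consumes.
#'
#' @param p0 Planned event proportion by the average follow-up, in (0, 1).
#' @param delta Design ratio; `delta < 1` monitors for an event-rate shortfall,
#'   `delta > 1` for an excess (safety monitoring).  Default 0.75, a common
#'   choice in informal monitoring practice.
#' @param alpha,beta Nominal type I and type II error rates of the SPRT.
#' @param n0 Planned accrual size (number of patients, >= 1).
#' @param T0 Recruitment period in days (> 0).
#' @param Tf Minimum follow-up period in days (>= 0); the end of study is
#'   `T = T0 + Tf`.
#' @param lam Optional Poisson accrual intensity (patients/day).  Informational
#'   only: simulations condition on `n0` patients recruited by `T0`.
#' @return An object of class `serm_design`.
#' @examples
#' serm_design(p0 = 0.15, delta = 0.75, n0 = 4600, T0 = 1095, Tf = 730)
#' @export
serm_design <- function(p0, delta = 0.75, alpha = 0.05, beta = 0.10,
                        n0, T0, Tf, lam = NULL) {
  .check_prob(p0, "p0")
  .check_prob(alpha, "alpha")
  .check_prob(beta, "beta")
  if (!is.numeric(delta) || delta <= 0) .stop_invalid("delta", "must be > 0")
  if (delta * p0 >= 1) .stop_invalid("delta", "gives delta * p0 >= 1")
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1 || n0 != round(n0))
    .stop_invalid("n0", "must be a positive integer")
  if (!is.numeric(T0) || T0 <= 0) .stop_invalid("T0", "must be > 0")
  if (!is.numeric(Tf) || Tf < 0) .stop_invalid("Tf", "must be >= 0")
  if (!is.null(lam) && (!is.numeric(lam) || lam <= 0))
    .stop_invalid("lam", "must be NULL or > 0")
  structure(
    list(p0 = p0, delta = delta, alpha = alpha, beta = beta,
         n0 = as.integer(n0), T0 = T0, Tf = Tf, lam = lam),
    class = "serm_design")
}

#' Derive the transformed design quantities
#'
#' Computes from a [serm_design()] the quantities on which the sequential test
#' operates: the average follow-up `Ta = T - T0/2` (patients enter uniformly
#' over the recruitment period, so the average entry time is `T0/2`), the null
#' and alternative hazards `theta0`, `theta1` matching the event proportions
#' `p0` and `delta * p0` by `Ta`, and the effective ratio
#' `delta_star = theta1 / theta0`.  Multiplying all times (entry and survival)
#' by `theta0` reduces the null hypothesis to a unit exponential hazard; the
#' monitor applies this rescaling internally.
#'
#' @param design A `serm_design` object.
#' @return An object of class `serm_derived` with fields `delta_star`,
#'   `theta0`, `theta1`, `Ta`, `T`, and the originating `design`.
#' @examples
#' derive_design(serm_design(p0 = 0.15, n0 = 4600, T0 = 1095, Tf = 730))
#' @export
derive_design <- function(design) {
  if (inherits(design, "serm_derived")) return(design)
  stopifnot(inherits(design, "serm_design"))
  Tend <- design$T0 + design$Tf
  Ta <- Tend - design$T0 / 2
  theta0 <- hazard_from_proportion(design$p0, Ta)
  theta1 <- hazard_from_proportion(design$delta * design$p0, Ta)
  structure(
    list(delta_star = effective_ratio(design$p0, design$delta),
         theta0 = theta0, theta1 = theta1, Ta = Ta, T = Tend,
         design = design),
    class = "serm_derived")
}

#' @export
print.serm_design <- function(x, ...) {
  cat("Sequential event-rate monitoring design\n")
  cat(sprintf("  p0 = %.4g, delta = %.4g, alpha = %.3g, beta = %.3g\n",
              x$p0, x$delta, x$alpha, x$beta))
  cat(sprintf("  accrual n0 = %d over T0 = %g d; minimum follow-up Tf = %g d\n",
              x$n0, x$T0, x$Tf))
  if (!is.null(x$lam)) cat(sprintf("  accrual intensity lam = %.4g /d\n", x$lam))
  invisible(x)
}

#' @export
print.serm_derived <- function(x, ...) {
  print(x$design)
  cat("Derived quantities\n")
  cat(sprintf("  end of study T = %g d, average follow-up Ta = %g d\n", x$T, x$Ta))
  cat(sprintf("  theta0 = %.6g /d, theta1 = %.6g /d, delta* = %.4f\n",
              x$theta0, x$theta1, x$delta_star))
  invisible(x)
}
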