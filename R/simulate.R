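## Synthetic-trial generator.  Entries are sorted uniforms on [0, T0]
## (the distribution of Poisson-process arrival times conditional on the
## accrual count), lifetimes are exponential or Weibull on the rescaled
## scale, and optional loss to follow-up is an independent exponential.

#' Describe the data-generating truth of a simulated trial
#'
#' @param family `"exponential"` or `"weibull"` lifetime family.
#' @param true_ratio Hazard multiplier applied to the null hazard `theta0`:
#'   1 generates data on target (the null), the design ratio `delta` generates
#'   the alternative, and other values support misspecification studies.  For
#'   the Weibull family the multiplier scales the cumulative hazard
#'   (proportional hazards).
#' @param weibull_shape Weibull shape `k` (> 0); 1 recovers the exponential.
#' @param weibull_rate Weibull rate `r` on the rescaled time scale, with
#'   survival `S(t) = exp(-true_ratio * (r t)^k)`; under shape 1, rate 1 and
#'   `true_ratio = 1` this is the unit-hazard null.
#' @param censor_prop Fraction of lifetimes lost to follow-up, in \[0, 1):
#'   an independent exponential censoring time is drawn with the rate that
#'   makes `P(censoring precedes event) = censor_prop`.
#' @return An object of class `serm_truth`.
#' @examples
#' truth_spec()                              # on-target exponential, no losses
#' truth_spec(true_ratio = 0.75)             # alternative
#' truth_spec("weibull", weibull_shape = 0.95, weibull_rate = 1.05)
#' @export
truth_spec <- function(family = c("exponential", "weibull"), true_ratio = 1,
                       weibull_shape = 1, weibull_rate = 1, censor_prop = 0) {
  family <- match.arg(family)
  if (!is.numeric(true_ratio) || true_ratio <= 0)
    stop("`true_ratio` must be > 0", call. = FALSE)
  if (!is.numeric(weibull_shape) || weibull_shape <= 0)
    stop("`weibull_shape` must be > 0", call. = FALSE)
  if (!is.numeric(weibull_rate) || weibull_rate <= 0)
    stop("`weibull_rate` must be > 0", call. = FALSE)
  if (!is.numeric(censor_prop) || censor_prop < 0 || censor_prop >= 1)
    stop("`censor_prop` must lie in [0, 1)", call. = FALSE)
  structure(list(family = family, true_ratio = true_ratio,
                 weibull_shape = weibull_shape, weibull_rate = weibull_rate,
                 censor_prop = censor_prop),
            class = "serm_truth")
}

#' Exponential censoring rate for a target censoring proportion
#'
#' For independent exponential lifetime (rate `theta`) and censoring (rate
#' `c`) times, `P(censoring before event) = c / (c + theta)`.  Solving for a
#' target proportion `q` gives `c = theta * q / (1 - q)`.
#'
#' @param theta Event hazard rate (> 0).
#' @param censor_prop Target censoring proportion in \[0, 1).
#' @return The censoring hazard rate.
#' @examples
#' censoring_rate(1, 0.2)   # 0.25
#' @export
censoring_rate <- function(theta, censor_prop) {
  if (!is.numeric(theta) || theta <= 0) stop("`theta` must be > 0",
                                             call. = FALSE)
  if (!is.numeric(censor_prop) || censor_prop < 0 || censor_prop >= 1)
    stop("`censor_prop` must lie in [0, 1)", call. = FALSE)
  theta * censor_prop / (1 - censor_prop)
}

# rescaled lifetimes with survival exp(-true_ratio * (rate t)^shape);
# exponential family is shape = rate = 1
.r_lifetime <- function(n, truth) {
  if (truth$family == "exponential")
    stats::rexp(n, rate = truth$true_ratio)
  else
    (stats::rexp(n, rate = truth$true_ratio))^(1 / truth$weibull_shape) /
      truth$weibull_rate
}

#' Simulate one trial's patient table
#'
#' Generates `n0` entry times as sorted uniforms on `[0, T0]`, lifetimes from
#' the truth family (on the rescaled scale, converted back to days through
#' `theta0`), and, when `censor_prop > 0`, independent exponential loss to
#' follow-up.  Administrative censoring at the end of study is *not* applied
#' here: it is implicit in the monitor's exposure computation, so the recorded
#' `duration_days` is the full time from entry to event or loss.
#'
#' @param design A `serm_design` or `serm_derived` object.
#' @param truth A [truth_spec()]; default is the on-target exponential null
#'   with no losses.
#' @param seed RNG seed (required; the output is fully reproducible).
#' @return A data frame with columns `patient_id`, `entry_day` (sorted),
#'   `duration_days`, `event` (logical; `FALSE` = lost to follow-up).
#' @examples
#' des <- serm_design(p0 = 0.25, n0 = 800, T0 = 365, Tf = 1095)
#' head(simulate_trial(des, seed = 1))
#' @export
simulate_trial <- function(design, truth = truth_spec(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  dd <- derive_design(design)
  stopifnot(inherits(truth, "serm_truth"))
  n0 <- dd$design$n0
  .with_seed(seed, {
    entry <- sort(stats::runif(n0, 0, dd$design$T0))
    life <- .r_lifetime(n0, truth) / dd$theta0           # days
    if (truth$censor_prop > 0) {
      crate <- censoring_rate(truth$true_ratio, truth$censor_prop)
      cens <- stats::rexp(n0, rate = crate) / dd$theta0
      event <- life <= cens
      dur <- pmin(life, cens)
    } else {
      event <- rep(TRUE, n0)
      dur <- life
    }
    data.frame(patient_id = seq_len(n0), entry_day = entry,
               duration_days = dur, event = event)
  })
}
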