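## Operating-characteristics studies: distributions of the stopping time and
## of the event count at stopping, empirical error rates, behaviour under a
## misspecified event-rate ratio, Weibull sensitivity, and the minimum-accrual
## search.  Replications are independent given deterministic per-replication
## child seeds, so any execution order gives identical aggregates.

.child_seed <- function(root, i) {
  as.integer((as.double(root) * 1009 + as.double(i) * 7919) %% 2147483562) + 1L
}

#' Benchmark grid of phase III monitoring scenarios
#'
#' The standard evaluation grid used by the operating-characteristics studies:
#' ten event proportions `p0` from 0.05 to 0.50, each paired with the accrual
#' size whose completion rate reaches 99.5% (patients almost always yield a
#' decision by the end of study), crossed with three recruitment/follow-up
#' splits (1+3, 2+2, 3+1 years).  All scenarios use `alpha = 0.05`,
#' `beta = 0.10`, `delta = 0.75`.
#'
#' @return A data frame with columns `p0`, `n0`, `T0`, `Tf`.
#' @export
serm_scenarios <- function() {
  base <- data.frame(
    p0 = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50),
    n0 = c(4500, 2200, 1400, 1000, 800, 600, 500, 400, 350, 300))
  splits <- data.frame(T0 = c(365, 730, 1095), Tf = c(1095, 730, 365))
  out <- merge(base, splits)
  out[order(out$p0, out$T0), c("p0", "n0", "T0", "Tf")]
}

# one simulated trial monitored to a decision; returns
# c(decision 0/1/2, stopping day, events at stop, patients at stop)
.trial_outcome <- function(dd, bounds, truth, seed, followup_interval = 1) {
  rec <- simulate_trial(dd, truth, seed)
  m <- run_monitor(rec, dd, bounds, followup_interval = followup_interval,
                   keep_path = FALSE)
  dec <- switch(m$decision, accept_H1_upper = 1, accept_H0_lower = 2, 0)
  c(dec, m$stopping_day, m$events_at_stop, m$n_at_stop)
}

#' Simulate one monitoring scenario repeatedly and summarise
#'
#' Workhorse behind the study functions: simulates `reps` trials under a
#' given truth and runs the monitor to a decision in each.  Stopping-time and
#' event summaries are taken over decided replications only; inconclusive
#' runs (no crossing by the end of study) count against the completion rate.
#'
#' @param design A `serm_design` or `serm_derived`.
#' @param truth A [truth_spec()].
#' @param reps Number of replications (>= 1).
#' @param seed Root seed; replication `r` uses a deterministic child seed.
#' @param boundaries Optional `serm_boundaries` override.
#' @param followup_interval Passive follow-up evaluation spacing in days.
#' @return An object of class `serm_scenario_result`: one-row data frame with
#'   the scenario parameters, `reps`, `prob_accept_H1`, `prob_accept_H0`,
#'   `prob_inconclusive`, `completion_rate`, `mean_stop_days`, `sd_stop_days`,
#'   `mean_events`, `sd_events`.
#' @export
run_scenario <- function(design, truth = truth_spec(), reps, seed,
                         boundaries = NULL, followup_interval = 1) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(reps) || reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  dd <- derive_design(design)
  if (is.null(boundaries)) boundaries <- serm_boundaries(dd)
  out <- vapply(seq_len(reps), function(r)
    .trial_outcome(dd, boundaries, truth, .child_seed(seed, r),
                   followup_interval),
    numeric(4))
  dec <- out[1L, ]
  ok <- dec > 0
  res <- data.frame(
    p0 = dd$design$p0, n0 = dd$design$n0, T0 = dd$design$T0,
    Tf = dd$design$Tf, delta = dd$design$delta, alpha = dd$design$alpha,
    beta = dd$design$beta, family = truth$family,
    true_ratio = truth$true_ratio, reps = as.integer(reps),
    prob_accept_H1 = mean(dec == 1), prob_accept_H0 = mean(dec == 2),
    prob_inconclusive = mean(dec == 0), completion_rate = mean(ok),
    mean_stop_days = mean(out[2L, ok]), sd_stop_days = stats::sd(out[2L, ok]),
    mean_events = mean(out[3L, ok]), sd_events = stats::sd(out[3L, ok]))
  class(res) <- c("serm_scenario_result", "data.frame")
  res
}

.as_design_rows <- function(scenarios, delta = 0.75, alpha = 0.05,
                            beta = 0.10) {
  lapply(seq_len(nrow(scenarios)), function(i)
    serm_design(p0 = scenarios$p0[i], delta = delta, alpha = alpha,
                beta = beta, n0 = scenarios$n0[i], T0 = scenarios$T0[i],
                Tf = scenarios$Tf[i]))
}

#' Stopping-time study under the on-target event rate
#'
#' For each scenario, simulates trials under the null truth (event rate on
#' target) and summarises the distribution of the stopping day and of the
#' number of primary events observed at stopping.
#'
#' @param scenarios Data frame with columns `p0`, `n0`, `T0`, `Tf` (see
#'   [serm_scenarios()]).
#' @param reps Replications per scenario.
#' @param seed Root seed; scenario `i` uses child seed `i`.
#' @param delta,alpha,beta Design parameters shared by all scenarios.
#' @param truth Truth specification; default the exponential null.
#' @return A data frame with one [run_scenario()] summary row per scenario.
#' @export
stopping_time_study <- function(scenarios, reps = 10000, seed,
                                delta = 0.75, alpha = 0.05, beta = 0.10,
                                truth = truth_spec()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  designs <- .as_design_rows(scenarios, delta, alpha, beta)
  rows <- lapply(seq_along(designs), function(i)
    run_scenario(designs[[i]], truth, reps, .child_seed(seed, i)))
  do.call(rbind, rows)
}

#' Empirical type I and type II error study
#'
#' Type I error is the fraction of null-truth replications whose statistic
#' first crosses the upper threshold; type II error is the fraction of
#' alternative-truth replications first crossing the lower threshold.  The
#' alternative truth is the exact alternative hypothesis `p = delta * p0`,
#' i.e. lifetimes at hazard ratio `delta_star = effective_ratio(p0, delta)`
#' relative to the null hazard.
#'
#' @inheritParams stopping_time_study
#' @return A data frame with columns `p0`, `n0`, `T0`, `Tf`, `type1`, `type2`
#'   plus the two underlying scenario summaries' acceptance probabilities.
#' @export
error_study <- function(scenarios, reps = 5000, seed, delta = 0.75,
                        alpha = 0.05, beta = 0.10) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  designs <- .as_design_rows(scenarios, delta, alpha, beta)
  rows <- lapply(seq_along(designs), function(i) {
    null_run <- run_scenario(designs[[i]], truth_spec(), reps,
                             .child_seed(seed, 2L * i - 1L))
    ds <- effective_ratio(scenarios$p0[i], delta)
    alt_run <- run_scenario(designs[[i]], truth_spec(true_ratio = ds),
                            reps, .child_seed(seed, 2L * i))
    data.frame(p0 = scenarios$p0[i], n0 = scenarios$n0[i],
               T0 = scenarios$T0[i], Tf = scenarios$Tf[i], reps = reps,
               type1 = null_run$prob_accept_H1,
               type2 = alt_run$prob_accept_H0,
               null_prob_accept_H0 = null_run$prob_accept_H0,
               alt_prob_accept_H1 = alt_run$prob_accept_H1)
  })
  do.call(rbind, rows)
}

#' Behaviour under a misspecified true event-rate ratio
#'
#' Keeps the boundaries designed for `delta` (default 0.75) but generates
#' lifetimes at other hazard multipliers (default 0.5 and 2.0).  Reports, per
#' scenario and truth ratio, the acceptance probabilities and the mean
#' stopping time as a percentage of the same scenario's null-truth mean.
#'
#' @inheritParams stopping_time_study
#' @param true_ratios Hazard multipliers to study.
#' @return A data frame with one row per (scenario, true ratio):
#'   `prob_accept_H1`, `prob_accept_H0`, `mean_stop_days`,
#'   `null_mean_stop_days`, `stop_pct_of_null`.
#' @export
misspecification_study <- function(scenarios, true_ratios = c(0.5, 2.0),
                                   reps = 2000, seed, delta = 0.75,
                                   alpha = 0.05, beta = 0.10) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  designs <- .as_design_rows(scenarios, delta, alpha, beta)
  rows <- list()
  for (i in seq_along(designs)) {
    null_run <- run_scenario(designs[[i]], truth_spec(), reps,
                             .child_seed(seed, 1000L + i))
    for (j in seq_along(true_ratios)) {
      r <- true_ratios[j]
      run <- run_scenario(designs[[i]], truth_spec(true_ratio = r), reps,
                          .child_seed(seed, i * 100L + j))
      rows[[length(rows) + 1L]] <- data.frame(
        p0 = scenarios$p0[i], n0 = scenarios$n0[i], T0 = scenarios$T0[i],
        Tf = scenarios$Tf[i], true_ratio = r, reps = reps,
        prob_accept_H1 = run$prob_accept_H1,
        prob_accept_H0 = run$prob_accept_H0,
        mean_stop_days = run$mean_stop_days,
        null_mean_stop_days = null_run$mean_stop_days,
        stop_pct_of_null = 100 * run$mean_stop_days / null_run$mean_stop_days)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity of the error rates to Weibull lifetimes
#'
#' Generates lifetimes from Weibull distributions (boundaries still computed
#' under the exponential working model) and reports empirical type I and
#' type II errors per (shape, rate) pair.
#'
#' @param shape_rate Data frame with columns `shape` and `rate`.
#' @param design A single `serm_design` giving the trial scenario.
#' @param reps Replications per truth.
#' @param seed Root seed.
#' @return A data frame with columns `shape`, `rate`, `type1`, `type2`.
#' @export
sensitivity_study <- function(shape_rate, design, reps = 2000, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  dd <- derive_design(design)
  rows <- lapply(seq_len(nrow(shape_rate)), function(i) {
    k <- shape_rate$shape[i]; r <- shape_rate$rate[i]
    null_run <- run_scenario(
      dd, truth_spec("weibull", true_ratio = 1, weibull_shape = k,
                     weibull_rate = r),
      reps, .child_seed(seed, 2L * i - 1L))
    alt_run <- run_scenario(
      dd, truth_spec("weibull", true_ratio = dd$delta_star,
                     weibull_shape = k, weibull_rate = r),
      reps, .child_seed(seed, 2L * i))
    data.frame(shape = k, rate = r, reps = reps,
               type1 = null_run$prob_accept_H1,
               type2 = alt_run$prob_accept_H0)
  })
  do.call(rbind, rows)
}

#' Smallest accrual size reaching a target completion rate
#'
#' Searches a grid of accrual sizes for the smallest `n0` whose estimated
#' completion rate (fraction of null-truth replications reaching a decision
#' by the end of study) is at least `target`.  The completion rate is
#' monotone non-decreasing in `n0`, so the first grid point over the target
#' is returned.
#'
#' @param p0 Planned event proportion.
#' @param T0,Tf Recruitment and minimum follow-up periods (days).
#' @param reps Replications per candidate `n0`.
#' @param seed Root seed.
#' @param target Required completion rate; default 0.995.
#' @param n0_grid Candidate accrual sizes; default `seq(50, 5000, by = 50)`.
#' @param delta,alpha,beta Design parameters.
#' @return A list with `n0` (the solution), `completion_rate` at the
#'   solution, and `trace` (a data frame of all candidates tried).
#' @export
find_min_n0 <- function(p0, T0, Tf, reps = 500, seed, target = 0.995,
                        n0_grid = seq(50, 5000, by = 50), delta = 0.75,
                        alpha = 0.05, beta = 0.10) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  trace <- data.frame(n0 = integer(), completion_rate = numeric())
  for (i in seq_along(n0_grid)) {
    n0 <- n0_grid[i]
    des <- serm_design(p0 = p0, delta = delta, alpha = alpha, beta = beta,
                       n0 = n0, T0 = T0, Tf = Tf)
    run <- run_scenario(des, truth_spec(), reps, .child_seed(seed, i))
    trace <- rbind(trace,
                   data.frame(n0 = n0, completion_rate = run$completion_rate))
    if (run$completion_rate >= target)
      return(list(n0 = n0, completion_rate = run$completion_rate,
                  trace = trace))
  }
  stop(sprintf(
    "completion rate %.3f not reached for any n0 up to %d; last rate %.3f",
    target, max(n0_grid), trace$completion_rate[nrow(trace)]), call. = FALSE)
}
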