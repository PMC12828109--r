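## The sequential statistic.  In rescaled time (all durations multiplied by
## theta0) the log-likelihood ratio after n patients, evaluated at calendar
## time t, is
##     Lambda = K * log(delta_star) + (1 - delta_star) * Ttot
## where K counts observed events and Ttot is the total time on test: each
## entered patient contributes min(duration, t - entry).  Patients lost to
## follow-up contribute exposure up to censoring but never an event.

# Vectorised trajectory of (n, K, Ttot, Lambda) over sorted evaluation times.
# Counting-process bookkeeping: with entries e, follow-up terminations
# f = e + d, exposure at time t is
#   sum_{f_k <= t} d_k  +  t * #{e_k <= t < f_k}  -  sum_{e_k <= t < f_k} e_k,
# all obtainable from cumulative sums over the e- and f-sorted orders.
.lambda_path <- function(entry, duration, event, times, delta_star) {
  n <- length(entry)
  if (n == 0L) {
    z <- numeric(length(times))
    return(list(n = z, K = z, Ttot = z, Lambda = z))
  }
  fin <- entry + duration
  oe <- order(entry)
  es <- entry[oe]
  of <- order(fin)
  fs <- fin[of]
  cum_e <- cumsum(es)
  cum_d_f <- cumsum(duration[of])
  cum_e_f <- cumsum(entry[of])
  fe <- fs[event[of]]                      # event times, sorted
  ne <- findInterval(times, es)
  nf <- findInterval(times, fs)
  Ttot <- c(0, cum_d_f)[nf + 1L] + times * (ne - nf) -
    (c(0, cum_e)[ne + 1L] - c(0, cum_e_f)[nf + 1L])
  K <- findInterval(times, fe)
  list(n = ne, K = K, Ttot = Ttot,
       Lambda = K * log(delta_star) + (1 - delta_star) * Ttot)
}

#' Sequential statistic at a single time point (from-scratch oracle)
#'
#' Computes the monitoring state by direct summation over patient records at
#' one rescaled calendar time `t`: every patient with `entry <= t` contributes
#' `min(duration, t - entry)` to the total time on test, and contributes one
#' event iff the event indicator is set and `duration <= t - entry`.  This is
#' the reference definition of the statistic; [run_monitor()] computes the
#' same quantities incrementally over a whole evaluation grid.
#'
#' @param records Data frame with columns `entry`, `duration`, `event`
#'   (logical), all on the rescaled (dimensionless) time scale.
#' @param t Rescaled calendar time (>= 0).
#' @param delta_star Effective hazard ratio.
#' @return A list of class `serm_state`: `n` (patients entered), `K` (events),
#'   `Ttot` (total time on test), `Lambda` (the statistic), `t_now`.
#' @examples
#' rec <- data.frame(entry = c(0, 0.5), duration = c(0.3, 2), event = TRUE)
#' statistic_at(rec, t = 0.5, delta_star = 0.5)
#' @export
statistic_at <- function(records, t, delta_star) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("`t` must be a single non-negative time", call. = FALSE)
  if (nrow(records) == 0L)
    return(structure(list(n = 0L, K = 0L, Ttot = 0, Lambda = 0, t_now = t),
                     class = "serm_state"))
  entered <- records$entry <= t
  expo <- pmin(records$duration[entered], t - records$entry[entered])
  K <- sum(records$event[entered] &
             records$duration[entered] <= t - records$entry[entered])
  Ttot <- sum(expo)
  structure(list(n = sum(entered), K = as.integer(K), Ttot = Ttot,
                 Lambda = K * log(delta_star) + (1 - delta_star) * Ttot,
                 t_now = t),
            class = "serm_state")
}

# deterministic tie-breaking: duplicated entry days get a seeded uniform
# jitter on (0, 1e-6) days, far below any clinically meaningful resolution
.break_entry_ties <- function(entry_day, tie_seed = 1L) {
  dup <- duplicated(entry_day)
  if (!any(dup)) return(entry_day)
  jit <- .with_seed(tie_seed, stats::runif(sum(dup), 0, 1e-6))
  entry_day[dup] <- entry_day[dup] + jit
  entry_day
}

#' Run the sequential event-rate monitor over a patient table
#'
#' Evaluates the statistic at every patient-entry time during recruitment and
#' then at regular calendar intervals (default daily) until the end of study
#' `T = T0 + Tf`, stopping at the first evaluation where `Lambda > a` (accept
#' the alternative: the event rate appears off target) or `Lambda < -b`
#' (accept the null: the rate is on target).  Boundary comparisons are strict
#' inequalities.  If neither threshold is crossed by `T` the run is
#' inconclusive.
#'
#' Input times are in days; the function rescales them by `theta0` internally.
#' Tied entry days are split by a tiny seeded jitter (< 1e-6 days) so that
#' entry times are strictly ordered; decisions are invariant to the jitter on
#' generic data.
#'
#' @param records Data frame with columns `entry_day` (>= 0), `duration_days`
#'   (> 0, time from entry to event or censoring) and `event` (logical or
#'   0/1; censored records never count as events).
#' @param design A `serm_design` or `serm_derived` object.
#' @param boundaries A `serm_boundaries` object; defaults to
#'   [serm_boundaries]`(design)`.
#' @param followup_interval Calendar spacing (days) of evaluations during
#'   passive follow-up; default 1 (daily), 7 gives weekly updates.
#' @param tie_seed Seed for the entry-tie jitter.
#' @param keep_path If `FALSE`, the per-evaluation trajectory table is not
#'   assembled (used by the simulation studies for speed).
#' @return An object of class `serm_trajectory`: list with `path` (data frame
#'   `calendar_day`, `n`, `K`, `Ttot`, `Lambda`, truncated at the stopping
#'   evaluation), `decision` (`"accept_H1_upper"`, `"accept_H0_lower"` or
#'   `"inconclusive"`), `stopping_day`, `n_at_stop`, `events_at_stop`,
#'   `boundaries`, `design`.
#' @examples
#' des <- serm_design(p0 = 0.25, n0 = 100, T0 = 365, Tf = 365)
#' rec <- simulate_trial(des, seed = 7)
#' run_monitor(rec, des)
#' @export
run_monitor <- function(records, design, boundaries = NULL,
                        followup_interval = 1, tie_seed = 1L,
                        keep_path = TRUE) {
  dd <- derive_design(design)
  if (is.null(boundaries)) boundaries <- serm_boundaries(dd)
  stopifnot(inherits(boundaries, "serm_boundaries"))
  if (!is.numeric(followup_interval) || followup_interval <= 0)
    stop("`followup_interval` must be positive", call. = FALSE)
  req <- c("entry_day", "duration_days", "event")
  if (!all(req %in% names(records)))
    stop("`records` needs columns entry_day, duration_days, event",
         call. = FALSE)
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  if (any(!is.finite(records$entry_day)) || any(records$entry_day < 0))
    stop("entry days must be non-negative numbers", call. = FALSE)
  if (any(!is.finite(records$duration_days)) || any(records$duration_days <= 0))
    stop("durations must be positive numbers", call. = FALSE)

  entry <- .break_entry_ties(records$entry_day, tie_seed)
  ord <- order(entry)
  entry <- entry[ord]
  dur <- records$duration_days[ord]
  evt <- as.logical(records$event[ord])

  Tend <- dd$T
  last <- max(entry)
  grid <- entry[entry <= Tend]
  if (!length(grid))
    stop(sprintf("no entries on or before the end of study (day %g)", Tend),
         call. = FALSE)
  if (last < Tend)
    grid <- c(grid, seq(ceiling(last) + followup_interval, Tend,
                        by = followup_interval))
  if (grid[length(grid)] < Tend) grid <- c(grid, Tend)
  grid <- sort(unique(grid))

  th0 <- dd$theta0
  p <- .lambda_path(entry * th0, dur * th0, evt, grid * th0, dd$delta_star)
  hit <- which(p$Lambda > boundaries$a | p$Lambda < -boundaries$b)
  if (length(hit)) {
    i <- hit[1L]
    decision <- if (p$Lambda[i] > boundaries$a) "accept_H1_upper"
                else "accept_H0_lower"
    stopping_day <- grid[i]
    keep <- seq_len(i)
  } else {
    i <- length(grid)
    decision <- "inconclusive"
    stopping_day <- NA_real_
    keep <- seq_len(i)
  }
  path <- if (keep_path)
    data.frame(calendar_day = grid[keep], n = p$n[keep], K = p$K[keep],
               Ttot = p$Ttot[keep], Lambda = p$Lambda[keep])
  else NULL
  structure(
    list(path = path, decision = decision, stopping_day = stopping_day,
         n_at_stop = as.integer(p$n[i]), events_at_stop = as.integer(p$K[i]),
         boundaries = boundaries, design = dd),
    class = "serm_trajectory")
}

#' @export
print.serm_trajectory <- function(x, ...) {
  cat("Sequential event-rate monitoring run\n")
  cat(sprintf("  decision: %s\n", x$decision))
  if (!is.na(x$stopping_day))
    cat(sprintf("  stopped on day %.1f with %d patients and %d events\n",
                x$stopping_day, x$n_at_stop, x$events_at_stop))
  else
    cat(sprintf("  no boundary crossed by end of study (day %g)\n", x$design$T))
  cat(sprintf("  thresholds: a = %.4f, -b = %.4f\n",
              x$boundaries$a, -x$boundaries$b))
  invisible(x)
}

#' Monitoring chart for a trajectory
#'
#' Plots the statistic against calendar time with horizontal lines at the
#' upper threshold `a` and lower threshold `-b`.
#'
#' @param x A `serm_trajectory` from [run_monitor()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.serm_trajectory <- function(x, ...) {
  if (is.null(x$path)) stop("trajectory was run with keep_path = FALSE",
                            call. = FALSE)
  rng <- range(c(x$path$Lambda, x$boundaries$a, -x$boundaries$b))
  graphics::plot(x$path$calendar_day, x$path$Lambda, type = "l",
                 xlab = "days since first randomization",
                 ylab = expression(Lambda[n]), ylim = rng, ...)
  graphics::abline(h = c(x$boundaries$a, -x$boundaries$b), lty = 2,
                   col = "grey40")
  if (!is.na(x$stopping_day))
    graphics::points(x$stopping_day, x$path$Lambda[nrow(x$path)], pch = 19)
  invisible(x)
}
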