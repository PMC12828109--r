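# serm — Sequential Event Rate Monitoring for time-to-event trials

Trials with a time-to-event primary endpoint are powered by their number of
primary events.  During recruitment, though, the raw event count is almost
uninterpretable: with staggered entry nearly everyone is administratively
censored at any interim look.  `serm` monitors the *pooled event rate*
instead — continuously, on blinded data — and signals as soon as the evidence
favours either "the study is on track for its planned events" or "the event
rate is off target and corrective action may be needed".  It is aimed at
statisticians supporting Data Coordinating Centers and monitoring committees
of randomised trials, and applies equally to safety monitoring of an
adverse-event rate.

## The test

The planned event proportion `p0` by the average follow-up time
`Ta = T0/2 + Tf` and a design ratio `δ` (default 0.75) define hypotheses
`H0: p = p0` vs `H1: p = δ·p0`.  For exponential lifetimes these reduce, after
rescaling time by the null hazard `θ0 = −ln(1−p0)/Ta`, to unit hazard versus

    δ* = ln(1 − δ·p0) / ln(1 − p0).

The monitor tracks the log-likelihood ratio

    Λ = K·ln δ* + (1 − δ*)·T_tot

(`K` events, `T_tot` total time on test), updated at every patient entry and
daily during passive follow-up, until it leaves the interval `(−b, a)`.  The
thresholds

    a = ln((1−β)·γ1/α),   b = ln((1−α)·γ0/β)

sharpen Wald's classical pair with overshoot corrections `γ0`, `γ1` — Laplace
transforms of the limiting boundary excess from nonlinear renewal theory —
evaluated from a fitted closed form `γ = a1·sin(a2·δ*) + a3`
(`gamma_approx()`), or calibrated by simulation (`simulate_gamma()`).

## Worked example

```r
library(serm)

des <- serm_design(p0 = 0.25, delta = 0.75, n0 = 800, T0 = 365, Tf = 1095)
derive_design(des)
#> Derived quantities
#>   end of study T = 1460 d, average follow-up Ta = 1277.5 d
#>   theta0 = 0.000225191 /d, theta1 = 0.000162536 /d, delta* = 0.7218

serm_boundaries(des)
#> SPRT thresholds (alpha = 0.05, beta = 0.1)
#>   upper a = 2.6585, lower -b = -2.1430  (gamma1 = 0.7931, gamma0 = 0.8974)
#>   Wald baseline: a = 2.8904, -b = -2.2513

rec <- simulate_trial(des, seed = 42)       # an on-target synthetic trial
m <- run_monitor(rec, des)
m
#> Sequential event-rate monitoring run
#>   decision: accept_H0_lower
#>   stopped on day 230.2 with 515 patients and 18 events
#>   thresholds: a = 2.6585, -b = -2.1430
```

The thresholds are strictly inside Wald's, so the decision comes earlier at
the same nominal error rates.  Here the statistic down-crossed `−b` on day
230 after only 18 observed events: the pooled rate is consistent with the
planned 25%, i.e. the study looks on track for its planned number of primary
events.  (A lower crossing says nothing about the treatment contrast — that
remains a question for the trial's own analysis.)  An upper crossing would
instead have flagged a likely event shortfall.  `plot(m)` draws the
monitoring chart with the statistic and both thresholds;
`write_report(m, "run1")` writes the trajectory table and a JSON decision
summary.

Operating characteristics are one call each: `stopping_time_study()`,
`error_study()`, `misspecification_study()`, `sensitivity_study()` and
`find_min_n0()`, over the benchmark grid `serm_scenarios()` or any custom
scenario table.  A command-line wrapper for all of this is installed at
`system.file("cli", "serm.R", package = "serm")`.

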