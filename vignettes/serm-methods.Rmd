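---
title: "Sequential event-rate monitoring: model, boundaries and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential event-rate monitoring: model, boundaries and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serm)
```

## The monitoring problem

A time-to-event trial is powered through its number of primary events, not its
number of patients.  During active recruitment the raw event count is a poor
progress measure: with staggered entry almost every patient is
administratively censored at any interim look, so a low count may reflect
either a genuinely low event *rate* or simply short exposure.  `serm` monitors
the pooled (blinded) event rate instead, continuously, and raises a signal as
soon as the accumulating data favour either "the rate is on target" or "the
rate is too low (or too high) to deliver the planned events".

Because only the combined event process of all arms is used, monitoring can
run alongside any randomised design without touching the treatment code.

## From event proportions to an SPRT on a hazard

The design inputs are the planned event proportion $p_0$ by the average
follow-up time, a design ratio $\delta$ (default 0.75: a 25% shortfall is the
departure the monitor is powered to flag; $\delta > 1$ monitors an
adverse-event excess), nominal errors $\alpha, \beta$, the accrual size
$n_0$, the recruitment period $T_0$ and the minimum follow-up $T_f$.

Entries are modelled as uniform on $[0, T_0]$ (the arrival-time distribution
of a Poisson accrual process given its count), so the mean entry time is
$T_0/2$ and the average follow-up is $T_a = T - T_0/2$ with $T = T_0 + T_f$.
Lifetimes are taken exponential.  The hypotheses
$H_0: p = p_0$ versus $H_1: p = \delta p_0$ about the proportion of events
within $T_a$ are then equivalent to hypotheses about the hazard,
$\theta_j = -\ln(1 - \delta^j p_0) / T_a$, and after multiplying all times by
$\theta_0$, to $H_0: \theta^* = 1$ versus $H_1: \theta^* = \delta^*$ with

$$\delta^* = \frac{\ln(1 - \delta p_0)}{\ln(1 - p_0)}.$$

Note that $-\ln(1 - x)$ is convex with value 0 at 0, so the effective hazard
ratio amplifies the departure from unity: $\delta^* < \delta$ when
$\delta < 1$ and $\delta^* > \delta$ when $\delta > 1$ (e.g. $p_0 = 0.15$,
$\delta = 0.75$ gives $\delta^* = 0.734$).

On the rescaled scale the log-likelihood ratio over the first $n$ patients at
calendar time $t$ is

$$\Lambda = K \ln \delta^* + (1 - \delta^*)\, T_{\text{tot}},$$

with $K$ the number of observed events and $T_{\text{tot}}$ the total time on
test (each entered patient contributes the smaller of their follow-up
duration and $t - \text{entry}$).  A patient lost to follow-up contributes
exposure up to censoring and never an event; administrative censoring at $t$
is implicit in the minimum.  The monitor evaluates $\Lambda$ at every patient
entry during recruitment and on a regular calendar grid (default daily,
weekly supported) afterwards, stopping the first time $\Lambda > a$ (accept
$H_1$) or $\Lambda < -b$ (accept $H_0$).  Comparisons are strict, exactly as
the stopping rule is defined; in particular zero thresholds cannot fire at
the very first entry where $\Lambda = 0$ identically.

## Decision thresholds and the overshoot correction

Wald's thresholds $a = \ln\frac{1-\beta}{\alpha}$,
$b = \ln\frac{1-\alpha}{\beta}$ ignore the overshoot of $\Lambda$ beyond the
boundary at the first crossing and are conservative.  Nonlinear renewal
theory replaces them by

$$a = \ln\frac{(1-\beta)\,\gamma_1}{\alpha}, \qquad
  b = \ln\frac{(1-\alpha)\,\gamma_0}{\beta},$$

where $\gamma_0, \gamma_1 \in (0, 1)$ are the Laplace transforms
$E\,e^{-R}$ of the limiting excess $R$ over the lower boundary under the
null and the upper boundary under the alternative.  Both corrections shrink
the continuation region, so decisions come earlier than under Wald's pair at
the same nominal error rates.

`gamma_approx()` evaluates the fitted closed form
$\gamma_j = a_1 \sin(a_2\, \delta^*) + a_3$ with coefficients depending on
the hypothesis and on the range of $\delta^*$ ($[0.2, 0.8]$ for shortfall
designs, $[1.2, 2.0]$ for excess designs; see `gamma_coefficients()`).  The
gap around $\delta^* = 1$ is deliberately unsupported — the two hypotheses
merge there and no finite boundary is meaningful — and the package refuses to
extrapolate rather than guessing.  For the reference design $p_0 = 0.15$,
$\delta = 0.75$, $\alpha = 0.05$, $\beta = 0.10$ this yields
$\gamma_0 = 0.902$, $\gamma_1 = 0.802$ and thresholds $a = 2.67$,
$-b = -2.15$, against Wald's $2.89$ and $-2.25$.

### Monte-Carlo calibration

For designs outside the fitted ranges, `simulate_gamma()` estimates the
corrections directly.  Viewed at entry-driven updates with complete
follow-up, the statistic is a random walk with increments
$\ln \delta^* + (1 - \delta^*) X$, $X$ exponential with rate 1 (null walk,
drifts down for every $\delta^* \neq 1$) or rate $\delta^*$ (alternative
walk, drifts up).  The walk is run to first passage of a distant boundary
(default level 15; the excess distribution stabilises once the level is of
order 10, which the tests verify) and $E\,e^{-R}$ is averaged over
replications.  `fit_trig()` refits the sine form to a calibrated grid.

A known and deliberate limitation: the lower-boundary correction $\gamma_0$
from this walk agrees closely with the fitted sine values on $[0.2, 0.8]$
(within 0.04 at $\delta^* \in \{0.3, 0.5, 0.75\}$), because lower crossings
are genuine jumps of size $|\ln \delta^*|$ at events.  Upper crossings of
the staggered-entry statistic, however, ride an almost continuous exposure
ramp whose per-update increments are much smaller than the complete-data
walk's jumps, so their overshoot is smaller and the fitted $\gamma_1$ sits
0.06–0.12 *above* the walk-based estimate.  The walk calibration is
therefore a conservative cross-check for $\gamma_1$, not a drop-in
replacement for the fitted values; the fitted values are what
`serm_boundaries()` uses.

## The trial simulator

`simulate_trial()` implements the study conditions used throughout the
operating-characteristics suite:

* $n_0$ entries as sorted uniforms on $[0, T_0]$ (days);
* lifetimes on the rescaled scale with survival
  $S(t) = \exp\{-r_\theta\, (rt)^k\}$ — exponential is $k = r = 1$ — where
  the truth ratio $r_\theta$ is a proportional-hazards multiplier
  ($r_\theta = 1$: on target; $r_\theta = \delta^*$: the exact alternative
  $p = \delta p_0$; other values for misspecification studies).  The Weibull
  parameterisation is stated explicitly because shape/rate conventions vary:
  rate $r$ multiplies time inside the power;
* optional loss to follow-up as an independent exponential whose rate
  $c = \theta\, q/(1-q)$ yields censoring fraction $q$ exactly (default 0.2
  when censoring is requested — a common planning figure);
* one root seed, with deterministic per-replication child seeds, so any
  single replication is reproducible in isolation and aggregates are
  independent of execution order.

What the generator does *not* emulate: non-uniform accrual (ramp-up or
site-activation effects), secular changes in hazard, heterogeneity between
early and late enrollees, and reporting delay between an event and its
availability to the monitor.  Passing tests therefore certify the method
under idealised accrual and exponential (or mildly Weibull) lifetimes, not
under arbitrary real-trial conditions; the monitoring *decision* theory is
insensitive to accrual speed, but calendar quantities such as the mean
stopping day depend directly on the accrual pattern and clock conventions,
and should be interpreted with that sensitivity in mind.

## Operating characteristics

`serm_scenarios()` is the benchmark grid: $p_0$ from 0.05 to 0.50 paired
with accrual sizes 4500 down to 300 chosen so that at least 99.5% of
on-target trials reach a decision by $T$, crossed with recruitment/follow-up
splits of 1+3, 2+2 and 3+1 years.  On this grid, at the defaults
$\alpha = 0.05$, $\beta = 0.10$, $\delta = 0.75$:

* the expected number of events at stopping is modest (roughly 30–50) and
  depends mainly on $p_0$, barely on the calendar split;
* empirical type I error sits slightly above nominal (around 0.06) and type
  II slightly below nominal (around 0.10) — `error_study()` recomputes both;
  the type II simulation generates data under the exact alternative
  ($r_\theta = \delta^*$), since that is what the error is defined against;
* when the true ratio is far outside the tested pair (0.5 or 2.0 against
  boundaries designed for 0.75), the monitor picks the nearer hypothesis
  essentially always, in a little over half the on-target stopping time
  (`misspecification_study()`);
* under Weibull lifetimes with shapes near 1 the error rates barely move,
  while shapes well below 1 inflate type I error substantially — the method
  should not be used when early-hazard spikes are plausible
  (`sensitivity_study()`).

## Numerical and design choices

* **Tied entry days** are split by a seeded uniform jitter below $10^{-6}$
  days.  Ties carry no information here; the jitter only enforces the strict
  ordering the update indexing assumes, and decisions are invariant to it on
  generic data (property-tested).
* **Update grid.** Entry times plus a daily passive grid, with the end of
  study always included.  Weekly passive updates change the decision only
  through detection delay (at most the interval).
* **Incremental path vs oracle.** The production path computes the whole
  trajectory with counting-process cumulative sums and `findInterval`; the
  from-scratch `statistic_at()` is kept as an independent oracle and the two
  are required to agree to $10^{-9}$ on random record sets.
* **Seeds** are mandatory everywhere randomness occurs; there are no hidden
  RNG draws (the jitter uses its own seed and restores the caller's RNG
  state).
* **Degenerate inputs**: empty record sets give $\Lambda = 0$; designs with
  $\delta p_0 \ge 1$ are rejected, not clipped; $\gamma$ outside $(0, 1]$ is
  rejected; error rates too large for the requested corrections give a
  degenerate-boundary error rather than a negative threshold.
* **Problem sizes.** The packaged tests run the flagship scenarios at 1000 to
  2000 replications and the calibration checks at $10^5$ walks; these sizes
  put three Monte-Carlo standard errors well inside the effects being
  checked while keeping the default suite to a few minutes.  The acceptance
  script uses the same sizes.

## Limitations

The exponential working model is the real assumption: proportional changes
in a constant hazard.  Monitoring decisions made early extrapolate the
current rate to the whole study; secular trends or early/late-enrollee
heterogeneity undermine that extrapolation.  The blinded statistic says
nothing about treatment contrasts — a lower crossing means "enough events
are coming", never "the treatment works".  And the calendar scale of
stopping-time summaries (not the decisions or error rates) is tied to the
uniform-accrual, prompt-reporting idealisation described above.
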