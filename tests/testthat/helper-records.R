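# random day-scale patient record sets for oracle tests: entries inside the
# recruitment window, exponential durations of the order of the follow-up
random_records <- function(n, seed, T0, mean_dur, censor_frac = 0.3) {
  set.seed(seed)
  data.frame(
    entry_day = sort(runif(n, 0, T0)),
    duration_days = rexp(n, rate = 1 / mean_dur),
    event = runif(n) > censor_frac)
}

# the same records on the rescaled (dimensionless) scale used by the oracle
rescaled_records <- function(rec, theta0) {
  data.frame(entry = rec$entry_day * theta0,
             duration = rec$duration_days * theta0,
             event = rec$event)
}

# bare-bones boundary object for degenerate-threshold properties
fixed_boundaries <- function(a, b, alpha = 0.05, beta = 0.10) {
  structure(list(a = a, b = b, gamma0 = 1, gamma1 = 1,
                 alpha = alpha, beta = beta),
            class = "serm_boundaries")
}
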