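Package: serm
Title: Sequential Event Rate Monitoring for Time-to-Event Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous, blinded monitoring of the pooled primary event rate in
    time-to-event clinical trials with staggered entry, based on the sequential
    probability ratio test (SPRT). Event proportions are reduced to exponential
    hazards over the average follow-up, the log-likelihood-ratio statistic is
    tracked at every patient entry and on a regular calendar schedule during
    passive follow-up, and decision thresholds are narrowed relative to Wald's
    using Laplace-transform corrections for the boundary overshoot obtained from
    nonlinear renewal theory. Includes a trial simulator (uniform accrual,
    exponential or Weibull lifetimes, exponential loss to follow-up), an
    overshoot-calibration module, and an operating-characteristics suite for
    stopping times, empirical error rates, misspecified event-rate ratios,
    Weibull sensitivity, and minimum-accrual searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
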