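test_that("statistic matches hand-computed values", {
  rec <- data.frame(entry = c(0, 0.5), duration = c(0.3, 2.0), event = TRUE)
  s <- statistic_at(rec, t = 0.5, delta_star = 0.5)
  expect_equal(s$K, 1L)
  expect_equal(s$Ttot, 0.3)
  expect_equal(s$Lambda, log(0.5) + 0.5 * 0.3, tolerance = 1e-12)

  # a censored record adds exposure but never an event
  cens <- data.frame(entry = 0, duration = 0.2, event = FALSE)
  s2 <- statistic_at(cens, t = 1.0, delta_star = 0.5)
  expect_equal(s2$K, 0L)
  expect_equal(s2$Ttot, 0.2)
  expect_equal(s2$Lambda, 0.1, tolerance = 1e-12)

  # identical hypotheses carry no information
  s3 <- statistic_at(rec, t = 2, delta_star = 1)
  expect_equal(s3$Lambda, 0)
})

test_that("statistic handles empty input and rejects negative times", {
  empty <- data.frame(entry = numeric(), duration = numeric(),
                      event = logical())
  s <- statistic_at(empty, t = 1, delta_star = 0.7)
  expect_equal(s$n, 0L); expect_equal(s$Lambda, 0)
  expect_error(statistic_at(empty, t = -1, delta_star = 0.7), "non-negative")
})

test_that("monitor path equals the from-scratch oracle at every update", {
  des <- serm_design(p0 = 0.25, delta = 0.75, n0 = 25, T0 = 200, Tf = 200)
  dd <- derive_design(des)
  for (case in 1:25) {
    rec <- random_records(25, seed = 400 + case, T0 = 200, mean_dur = 400)
    m <- run_monitor(rec, dd, fixed_boundaries(Inf, Inf))
    resc <- rescaled_records(rec, dd$theta0)
    for (i in seq(1, nrow(m$path), by = 7)) {
      t_resc <- m$path$calendar_day[i] * dd$theta0
      oracle <- statistic_at(resc, t_resc, dd$delta_star)
      expect_equal(m$path$Lambda[i], oracle$Lambda, tolerance = 1e-9)
      expect_equal(m$path$K[i], oracle$K)
      expect_equal(m$path$Ttot[i], oracle$Ttot, tolerance = 1e-9)
    }
  }
})

test_that("exposure and event counts never decrease along the path", {
  des <- serm_design(p0 = 0.3, n0 = 60, T0 = 300, Tf = 400)
  rec <- simulate_trial(des, truth_spec(censor_prop = 0.2), seed = 3)
  m <- run_monitor(rec, des, fixed_boundaries(Inf, Inf))
  expect_true(all(diff(m$path$Ttot) >= -1e-12))
  expect_true(all(diff(m$path$K) >= 0))
  expect_equal(m$decision, "inconclusive")
})

test_that("degenerate thresholds decide immediately or never", {
  des <- serm_design(p0 = 0.3, n0 = 40, T0 = 300, Tf = 400)
  rec <- simulate_trial(des, seed = 8)
  never <- run_monitor(rec, des, fixed_boundaries(Inf, Inf))
  expect_equal(never$decision, "inconclusive")
  expect_true(is.na(never$stopping_day))
  # the statistic is exactly 0 at the very first entry (strict comparisons
  # cannot fire there), so zero thresholds decide at the next evaluation
  now <- run_monitor(rec, des, fixed_boundaries(0, 0))
  expect_lte(nrow(now$path), 2L)
  expect_false(now$decision == "inconclusive")
})

test_that("with zero events the monitor crosses at the exposure threshold", {
  # all-censored records: Lambda = (1 - delta*) * Ttot, so the upper
  # threshold is reached exactly when Ttot >= a / (1 - delta*)
  des <- serm_design(p0 = 0.50, n0 = 50, T0 = 10, Tf = 3000)
  dd <- derive_design(des)
  rec <- data.frame(entry_day = seq(0, 9, length.out = 50),
                    duration_days = 1e9, event = FALSE)
  bp <- serm_boundaries(des)
  m <- run_monitor(rec, des, bp)
  expect_equal(m$decision, "accept_H1_upper")
  need <- bp$a / (1 - dd$delta_star)            # rescaled exposure needed
  expo_at_stop <- m$path$Ttot[nrow(m$path)]
  expect_gte(expo_at_stop, need)
  # one daily step earlier the exposure was still below the requirement
  expect_lt(expo_at_stop - 50 * dd$theta0, need)
})

test_that("decisions are invariant to the tie-breaking jitter", {
  des <- serm_design(p0 = 0.25, n0 = 40, T0 = 200, Tf = 400)
  rec <- simulate_trial(des, seed = 12)
  rec$entry_day <- round(rec$entry_day)         # force many ties
  runs <- lapply(c(1, 99, 12345), function(s)
    run_monitor(rec, des, tie_seed = s))
  expect_equal(runs[[1]]$decision, runs[[2]]$decision)
  expect_equal(runs[[2]]$decision, runs[[3]]$decision)
  expect_equal(runs[[1]]$events_at_stop, runs[[3]]$events_at_stop)
})

test_that("row order of the patient table does not matter", {
  des <- serm_design(p0 = 0.25, n0 = 50, T0 = 200, Tf = 400)
  rec <- simulate_trial(des, seed = 14)
  shuffled <- rec[sample(nrow(rec)), ]
  m1 <- run_monitor(rec, des)
  m2 <- run_monitor(shuffled, des)
  expect_equal(m1$decision, m2$decision)
  expect_equal(m1$stopping_day, m2$stopping_day)
})

test_that("monitor validates its input", {
  des <- serm_design(p0 = 0.25, n0 = 5, T0 = 10, Tf = 10)
  bad <- data.frame(entry_day = c(-1, 2), duration_days = c(1, 1),
                    event = TRUE)
  expect_error(run_monitor(bad, des), "non-negative")
  bad2 <- data.frame(entry_day = c(1, 2), duration_days = c(0, 1),
                     event = TRUE)
  expect_error(run_monitor(bad2, des), "positive")
})
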