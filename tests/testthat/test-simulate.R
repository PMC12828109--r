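test_that("censoring rate solves the competing-exponentials identity", {
  expect_equal(censoring_rate(1, 0.2), 0.25, tolerance = 1e-12)
  expect_equal(censoring_rate(3.7, 0), 0)
  expect_equal(censoring_rate(2, 0.5), 2, tolerance = 1e-12)
  expect_error(censoring_rate(1, 1), "censor_prop")
  # P(censor first) = c / (c + theta) recovers the proportion
  for (q in c(0.1, 0.2, 0.4)) {
    cc <- censoring_rate(1.3, q)
    expect_equal(cc / (cc + 1.3), q, tolerance = 1e-12)
  }
})

test_that("simulated trials have the requested shape and are seeded", {
  des <- serm_design(p0 = 0.25, n0 = 800, T0 = 365, Tf = 1095)
  rec <- simulate_trial(des, seed = 77)
  expect_equal(nrow(rec), 800L)
  expect_true(all(rec$entry_day >= 0 & rec$entry_day <= 365))
  expect_true(!is.unsorted(rec$entry_day))
  expect_true(all(rec$event))
  expect_identical(rec, simulate_trial(des, seed = 77))
  expect_false(identical(rec, simulate_trial(des, seed = 78)))
})

test_that("entry times average half the recruitment period", {
  des <- serm_design(p0 = 0.25, n0 = 20000, T0 = 365, Tf = 1095)
  rec <- simulate_trial(des, seed = 5)
  se <- 365 / sqrt(12) / sqrt(20000)
  expect_lt(abs(mean(rec$entry_day) - 365 / 2), 4 * se)
})

test_that("null lifetimes give event proportion p0 by the average follow-up", {
  des <- serm_design(p0 = 0.25, n0 = 50000, T0 = 365, Tf = 1095)
  dd <- derive_design(des)
  rec <- simulate_trial(des, seed = 6)
  phat <- mean(rec$duration_days <= dd$Ta)
  expect_lt(abs(phat - 0.25), 4 * sqrt(0.25 * 0.75 / 50000))
})

test_that("empirical censoring fraction matches the requested proportion", {
  des <- serm_design(p0 = 0.25, n0 = 1e5, T0 = 365, Tf = 1095)
  rec <- simulate_trial(des, truth_spec(censor_prop = 0.2), seed = 15)
  se <- sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(mean(!rec$event) - 0.2), 3 * se)
})

test_that("Weibull with shape 1 and rate 1 reduces to the exponential", {
  des <- serm_design(p0 = 0.25, n0 = 500, T0 = 365, Tf = 1095)
  w <- simulate_trial(des, truth_spec("weibull", weibull_shape = 1,
                                      weibull_rate = 1), seed = 4)
  e <- simulate_trial(des, truth_spec("exponential"), seed = 4)
  expect_equal(w, e)
  # and a non-degenerate Weibull is genuinely different
  w2 <- simulate_trial(des, truth_spec("weibull", weibull_shape = 0.95,
                                       weibull_rate = 1.05), seed = 4)
  expect_false(isTRUE(all.equal(w2$duration_days, e$duration_days)))
})

test_that("alternative truth scales the cumulative hazard", {
  des <- serm_design(p0 = 0.25, n0 = 50000, T0 = 365, Tf = 1095)
  dd <- derive_design(des)
  rec <- simulate_trial(des, truth_spec(true_ratio = 0.75), seed = 16)
  target <- 1 - exp(-0.75 * dd$theta0 * dd$Ta)
  phat <- mean(rec$duration_days <= dd$Ta)
  expect_lt(abs(phat - target), 4 * sqrt(target * (1 - target) / 50000))
})

test_that("truth specification validates its inputs", {
  expect_error(truth_spec(true_ratio = 0), "true_ratio")
  expect_error(truth_spec(censor_prop = 1), "censor_prop")
  expect_error(truth_spec("weibull", weibull_shape = -1), "shape")
})
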