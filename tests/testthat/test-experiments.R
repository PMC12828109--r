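# small designs keep these replication tests fast; the full-scale
# operating-characteristics checks live in the acceptance suite

small_design <- function() serm_design(p0 = 0.4, n0 = 120, T0 = 200,
                                       Tf = 600)

test_that("the benchmark scenario grid pairs rates with accrual sizes", {
  sc <- serm_scenarios()
  expect_equal(nrow(sc), 30L)
  expect_equal(sort(unique(sc$p0)), seq(0.05, 0.5, by = 0.05))
  expect_true(all(sc$T0 + sc$Tf == 1460))
  expect_equal(unique(sc$n0[sc$p0 == 0.25]), 800)
  expect_equal(unique(sc$n0[sc$p0 == 0.50]), 300)
})

test_that("scenario summaries are coherent and reproducible", {
  r1 <- run_scenario(small_design(), reps = 60, seed = 2)
  expect_equal(r1$prob_accept_H1 + r1$prob_accept_H0 + r1$prob_inconclusive,
               1)
  expect_equal(r1$completion_rate, 1 - r1$prob_inconclusive)
  r2 <- run_scenario(small_design(), reps = 60, seed = 2)
  expect_identical(r1, r2)
  r3 <- run_scenario(small_design(), reps = 60, seed = 3)
  expect_false(identical(r1$mean_stop_days, r3$mean_stop_days))
  expect_error(run_scenario(small_design(), reps = 0, seed = 1), "reps")
})

test_that("error study returns both error rates per scenario", {
  sc <- data.frame(p0 = 0.4, n0 = 400, T0 = 200, Tf = 600)
  es <- error_study(sc, reps = 80, seed = 4)
  expect_equal(nrow(es), 1L)
  expect_true(es$type1 >= 0 && es$type1 <= 1)
  expect_true(es$type2 >= 0 && es$type2 <= 1)
  # under the null most runs should accept the null, and conversely
  expect_gt(es$null_prob_accept_H0, 0.5)
  expect_gt(es$alt_prob_accept_H1, 0.5)
})

test_that("a strongly misspecified rate drives fast, confident decisions", {
  sc <- data.frame(p0 = 0.4, n0 = 120, T0 = 200, Tf = 600)
  ms <- misspecification_study(sc, true_ratios = c(0.5, 2.0), reps = 100,
                               seed = 5)
  lo <- ms[ms$true_ratio == 0.5, ]
  hi <- ms[ms$true_ratio == 2.0, ]
  expect_gt(lo$prob_accept_H1, 0.9)
  expect_gt(hi$prob_accept_H0, 0.95)
  expect_lt(lo$stop_pct_of_null, 100)
  expect_lt(hi$stop_pct_of_null, 100)
})

test_that("Weibull sensitivity study reduces to the exponential at shape 1", {
  sr <- data.frame(shape = c(1, 0.6), rate = c(1, 1))
  sens <- sensitivity_study(sr, small_design(), reps = 80, seed = 6)
  base <- error_study(data.frame(p0 = 0.4, n0 = 120, T0 = 200, Tf = 600),
                      reps = 80, seed = 6)
  # shape 1 / rate 1 draws the same lifetimes as the exponential runs
  expect_equal(sens$type1[1], base$type1)
  expect_equal(sens$type2[1], base$type2)
})

test_that("minimum-accrual search stops at the first adequate size", {
  res <- find_min_n0(p0 = 0.5, T0 = 200, Tf = 600, reps = 60, seed = 7,
                     target = 0.9, n0_grid = c(20, 60, 120, 240, 480))
  expect_true(res$n0 %in% c(20, 60, 120, 240, 480))
  expect_gte(res$completion_rate, 0.9)
  # every earlier candidate fell short, and rates trend upward with n0
  earlier <- head(res$trace, -1)
  if (nrow(earlier)) expect_true(all(earlier$completion_rate < 0.9))
  expect_error(
    find_min_n0(p0 = 0.5, T0 = 200, Tf = 600, reps = 40, seed = 7,
                target = 0.9999, n0_grid = c(20, 40)),
    "not reached")
})

test_that("study drivers demand a seed", {
  sc <- data.frame(p0 = 0.4, n0 = 50, T0 = 100, Tf = 100)
  expect_error(stopping_time_study(sc, reps = 5), "seed")
  expect_error(error_study(sc, reps = 5), "seed")
})
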