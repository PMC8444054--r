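test_that("MAPE matches hand-computed values and is zero iff series agree", {
  sim <- data.frame(year = 2011:2012, suicides = c(100, 200))
  obs_eq <- data.frame(metric = "suicides", year = 2011:2012,
                       value = c(100, 200))
  expect_equal(mape(obs_eq, sim), 0)
  obs1 <- data.frame(metric = "suicides", year = 2011, value = 100)
  sim1 <- data.frame(year = 2011, suicides = 90)
  expect_equal(mape(obs1, sim1), 10)
  obs2 <- data.frame(metric = "suicides", year = 2011:2012,
                     value = c(100, 200))
  sim2 <- data.frame(year = 2011:2012, suicides = c(110, 190))
  expect_equal(mape(obs2, sim2), 7.5)
  expect_gt(mape(obs2, data.frame(year = 2011:2012,
                                  suicides = c(100.01, 200))), 0)
})

test_that("MAPE alignment failures name the metric and year", {
  sim <- data.frame(year = 2011, suicides = 100)
  expect_error(
    mape(data.frame(metric = "ed_presentations", year = 2011, value = 5), sim),
    "ed_presentations"
  )
  expect_error(
    mape(data.frame(metric = "suicides", year = 2015, value = 5), sim),
    "2015"
  )
  expect_error(
    mape(data.frame(metric = "suicides", year = 2011, value = 0), sim),
    "positive"
  )
})

test_that("the direction-set minimiser solves smooth bounded problems", {
  # separable quadratic: minimum inside the box
  f <- function(x) sum((x - c(1, -2, 3))^2)
  res <- powell_minimize(f, x0 = c(0, 0, 0), lower = c(-5, -5, -5),
                         upper = c(5, 5, 5))
  expect_true(res$converged)
  expect_equal(res$par, c(1, -2, 3), tolerance = 1e-3)
  # correlated valley (scaled two-parameter banana)
  g <- function(x) (1 - x[1])^2 + 5 * (x[2] - x[1]^2)^2
  res2 <- powell_minimize(g, x0 = c(-1, 1), lower = c(-2, -2),
                          upper = c(2, 3), maxit = 500)
  expect_equal(res2$par, c(1, 1), tolerance = 5e-2)
  # constrained minimum lands on the active bound
  res3 <- powell_minimize(function(x) (x - 4)^2, x0 = 0.5, lower = -1,
                          upper = 2)
  expect_equal(res3$par, 2, tolerance = 1e-4)
  expect_true(all(res3$par >= -1 & res3$par <= 2))
})

test_that("calibration problems validate their bounds and paths", {
  p <- catchment_parameters()
  obs <- data.frame(metric = "suicides", year = 2011, value = 10)
  expect_error(
    calibration_problem(p, data.frame(path = "nope", lower = 0, upper = 1,
                                      init = 0.5), obs),
    "unknown parameter path"
  )
  expect_error(
    calibration_problem(p, data.frame(path = "help_seeking_rate", lower = 1,
                                      upper = 0, init = 0.5), obs),
    "lower < upper"
  )
  expect_error(
    calibration_problem(p, data.frame(path = "help_seeking_rate", lower = 0,
                                      upper = 1, init = 2), obs),
    "outside bounds"
  )
})

test_that("zero free parameters returns the fixed parameters and their MAPE", {
  p <- catchment_parameters()
  obs <- generate_observed_series(p, 2011:2015, noise_cv = 0)
  prob <- calibration_problem(p, data.frame(path = character(),
                                            lower = numeric(),
                                            upper = numeric(),
                                            init = numeric()), obs)
  fit <- calibrate(prob, time_grid("2011-01-01", 5, 8))
  expect_lt(fit$mape, 1e-8)
  expect_identical(fit$iterations, 0L)
})

recovery_problem <- function(noise_cv = 0, seed = 42) {
  p_true <- catchment_parameters("truth")
  obs <- generate_observed_series(p_true, 2011:2020, noise_cv = noise_cv,
                                  seed = seed)
  free <- data.frame(
    path = c("distress_onset_rate", "help_seeking_rate",
             "attempt_rate_distressed_untreated"),
    lower = c(0.009, 0.012, 3.6e-4),
    upper = c(0.0225, 0.030, 9.0e-4),
    init = c(0.0172, 0.0176, 7.1e-4)
  )
  list(problem = calibration_problem(p_true, free, obs),
       truth = c(p_true$distress_onset_rate, p_true$help_seeking_rate,
                 p_true$attempt_rate_distressed_untreated))
}

test_that("noise-free synthetic series recover the generating parameters", {
  rp <- recovery_problem(noise_cv = 0)
  fit <- calibrate(rp$problem, time_grid("2011-01-01", 10, 8))
  expect_lt(max(abs(fit$estimates - rp$truth) / rp$truth), 0.01)
  expect_lt(fit$mape, 0.5)
  # monotone improvement and bound feasibility
  expect_lte(fit$mape, fit$initial_mape)
  expect_true(all(fit$estimates >= rp$problem$free$lower &
                    fit$estimates <= rp$problem$free$upper))
})

test_that("5% observation noise still recovers parameters within 10%", {
  rp <- recovery_problem(noise_cv = 0.05, seed = 42)
  fit <- calibrate(rp$problem, time_grid("2011-01-01", 10, 8))
  expect_lt(max(abs(fit$estimates - rp$truth) / rp$truth), 0.10)
})
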