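test_that("waiting time is queue over throughput, capped, and scales exactly", {
  expect_equal(waiting_time(100, 50), 2)
  expect_equal(waiting_time(0, 50), 0)
  expect_equal(waiting_time(100, 100), waiting_time(100, 50) / 2)
  expect_equal(waiting_time(1000, 0), 52)   # capacity gone -> capped, not Inf
  expect_equal(waiting_time(1e6, 1, cap = 10), 10)
})

test_that("compiled and reference engines produce the same trajectory", {
  p <- catchment_parameters()
  g <- time_grid("2011-01-01", 2, 8)
  tc <- simulate_catchment(p, g, engine = "cpp")
  tr <- simulate_catchment(p, g, engine = "r")
  expect_lt(max(abs(tc$states - tr$states) / (abs(tr$states) + 1)), 1e-10)
  expect_lt(max(abs(tc$aux - tr$aux)), 1e-10)
  # and with interventions active
  g5 <- time_grid("2019-01-01", 5, 8)
  tc2 <- simulate_catchment(p, g5, "awareness_campaign", engine = "cpp")
  tr2 <- simulate_catchment(p, g5, "awareness_campaign", engine = "r")
  expect_lt(max(abs(tc2$states - tr2$states) / (abs(tr2$states) + 1)), 1e-10)
})

test_that("an inert catchment does not move and reports all-zero metrics", {
  p <- inert_parameters()
  g <- time_grid("2011-01-01", 3, 8)
  traj <- simulate_catchment(p, g)
  expect_equal(traj$states[nrow(traj$states), ], traj$states[1, ])
  ym <- yearly_metrics(traj)
  for (m in c("suicides", "selfharm_hospitalisations", "ed_presentations",
              "gp_episodes", "disengagements")) {
    expect_equal(ym[[m]], rep(0, 3))
  }
})

test_that("living stocks track the demographic closure stock at every step", {
  p <- catchment_parameters()
  traj <- simulate_catchment(p, std_grid())
  pop <- rowSums(traj$states[, person_stocks()])
  expect_lt(max(abs(pop - traj$states[, "TotalPopulation"]) / pop), 1e-6)
})

test_that("constant per-capita demographic rates give exponential population growth", {
  p <- catchment_parameters(
    "demo", birth_rate = 2e-4, migration_rate = 1e-4,
    background_mortality = 1e-4,
    distress_onset_rate = 0, help_seeking_rate = 0,
    initial_distress_prevalence = 0,
    attempt_rate_distressed_untreated = 0, attempt_rate_in_care = 0,
    attempt_rate_postdischarge = 0, ed_presentation_rate = 0
  )
  g <- time_grid("2011-01-01", 10, 8)
  traj <- simulate_catchment(p, g)
  pop <- rowSums(traj$states[, person_stocks()])
  net <- 2e-4 + 1e-4 - 1e-4
  exact <- p$initial_population * exp(net * traj$times)
  expect_lt(max(abs(pop - exact) / exact), 0.005)
})

test_that("the two-state distress chain settles at onset/(onset+recovery)", {
  onset <- 0.01; recovery <- 0.03
  p <- two_state_parameters(onset, recovery, prev0 = 0.5)
  traj <- simulate_catchment(p, time_grid("2011-01-01", 10, 8))
  prev_end <- unname(traj$aux[nrow(traj$aux), "prevalence"])
  expect_equal(prev_end, onset / (onset + recovery), tolerance = 1e-3)
  # absorbing limit: no onset, positive recovery -> prevalence vanishes
  p0 <- two_state_parameters(0, 0.03, prev0 = 0.5)
  traj0 <- simulate_catchment(p0, time_grid("2011-01-01", 10, 8))
  expect_lt(traj0$aux[nrow(traj0$aux), "prevalence"], 1e-6)
})

test_that("prevalence stays within [0, 1] and yearly metrics are non-negative", {
  for (p in synthetic_state()[c(1, 5, 10)]) {
    traj <- simulate_catchment(p, std_grid())
    expect_true(all(traj$aux[, "prevalence"] >= 0 &
                      traj$aux[, "prevalence"] <= 1))
    ym <- yearly_metrics(traj)
    expect_true(all(as.matrix(ym[, -1]) >= -1e-9))
  }
})

test_that("a service with ample capacity keeps its queue near zero, a starved one grows a queue and sheds patients", {
  P <- 2e5
  slack <- catchment_parameters("slack", initial_population = P,
                                gp_capacity = 0.02 * P)
  g <- time_grid("2011-01-01", 5, 8)
  ts <- simulate_catchment(slack, g)
  n <- nrow(ts$states)
  expect_lt(ts$aux[n, "wait_gp"], 0.2)
  # steady-state throughput ~ inflow: queue stays bounded near zero
  expect_lt(ts$states[n, "WaitingGP"] / P, 0.005)

  starved <- catchment_parameters("starved", initial_population = P,
                                  gp_capacity = 0.0012 * P,
                                  capacity_growth = list(gp = 0))
  tt <- simulate_catchment(starved, g)
  expect_gt(tt$aux[n, "wait_gp"], 1)
  expect_gt(tt$states[n, "WaitingGP"], ts$states[n, "WaitingGP"] * 2)
  # disengagement flow is strictly positive under congestion
  expect_gt(diff(tt$states[c(1, n), "CumDisengagements"]),
            diff(ts$states[c(1, n), "CumDisengagements"]))
})

test_that("a single constant-hazard group accrues ~ N * r * f * T suicides", {
  r <- 1e-4; f <- 0.01; N <- 1e5
  p <- catchment_parameters(
    "hazard", initial_population = N, initial_distress_prevalence = 1,
    birth_rate = 0, migration_rate = 0, background_mortality = 0,
    distress_onset_rate = 0, distress_recovery_untreated = 0,
    help_seeking_rate = 0, ed_presentation_rate = 0,
    attempt_rate_distressed_untreated = r, attempt_rate_in_care = 0,
    attempt_rate_postdischarge = 0, hospitalisation_fraction = 0,
    case_fatality = f
  )
  traj <- simulate_catchment(p, time_grid("2011-01-01", 1, 8))
  got <- unname(traj$states[nrow(traj$states), "CumSuicides"])
  expect_equal(got, N * r * f * 52, tolerance = 0.01)
})

test_that("raising any service capacity never increases cumulative suicides", {
  p <- catchment_parameters()
  g <- time_grid("2011-01-01", 10, 8)
  base <- simulate_catchment(p, g)
  base_s <- base$states[nrow(base$states), "CumSuicides"]
  for (path in c("gp_capacity", "specialist_capacity", "cmhc_capacity",
                 "inpatient_capacity")) {
    q <- param_set(p, path, param_get(p, path) * 1.2)
    s <- simulate_catchment(q, g)$states[nrow(base$states), "CumSuicides"]
    expect_lte(s, base_s * (1 + 1e-9))
  }
})

test_that("cumulative stocks are non-decreasing and yearly sums telescope", {
  p <- synthetic_state()[[3]]
  traj <- simulate_catchment(p, time_grid("2011-01-01", 5, 8))
  for (stock in c("CumSuicides", "CumSelfHarmHosp", "CumEDPresentations",
                  "CumGPEpisodes", "CumDisengagements")) {
    expect_true(all(diff(traj$states[, stock]) >= -1e-12))
  }
  ym <- yearly_metrics(traj)
  expect_equal(sum(ym$suicides),
               diff(traj$states[c(1, nrow(traj$states)), "CumSuicides"]))
})

test_that("default parameterisations never trigger the negative-stock clamp", {
  expect_no_warning(simulate_catchment(catchment_parameters(), std_grid()))
  expect_no_warning(simulate_catchment(synthetic_state()[[10]], std_grid()))
})

test_that("a partial final year is excluded from yearly metrics with a warning", {
  p <- inert_parameters()
  g <- time_grid("2011-01-01", 2, 8)
  traj <- simulate_catchment(p, g)
  traj$states <- traj$states[1:(52 * 8 + 5), ]
  traj$aux <- traj$aux[1:(52 * 8 + 5), ]
  traj$times <- traj$times[1:(52 * 8 + 5)]
  expect_warning(ym <- yearly_metrics(traj), "partial")
  expect_identical(nrow(ym), 1L)
})
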