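test_that("the catalogue holds 13 interventions with valid effect paths", {
  cat13 <- default_catalogue()
  expect_length(cat13, 13)
  expect_identical(names(cat13),
                   unname(vapply(cat13, `[[`, character(1), "id")))
  known <- param_names_flat()
  for (iv in cat13) {
    for (e in iv$effects) expect_true(e$path %in% known)
    expect_equal(format(iv$start_date), "2021-01-01")
  }
  # three entries are flagged reconstructions
  expect_identical(sum(vapply(cat13, `[[`, logical(1), "reconstruction")), 3L)
})

test_that("intervention construction rejects malformed effects", {
  expect_error(intervention("a", "A", list()), "non-empty")
  expect_error(
    intervention("a", "A", list(list(path = "nope", mode = "multiply",
                                     magnitude = 0.5))),
    "unknown parameter path"
  )
  expect_error(
    intervention("a", "A", list(list(path = "help_seeking_rate",
                                     mode = "multiply", magnitude = 0))),
    "multiply magnitudes"
  )
  expect_error(intervention_set(c("post_attempt_care", "post_attempt_care")),
               "duplicate")
  expect_error(intervention_set("bogus"), "unknown intervention")
})

test_that("the empty set reproduces the baseline bit for bit", {
  p <- catchment_parameters()
  g <- time_grid("2019-01-01", 4, 8)
  base <- simulate_catchment(p, g, interventions = NULL)
  empty <- simulate_catchment(p, g, interventions = character())
  expect_identical(base$states, empty$states)
})

test_that("effects are inert before the start date and ramp linearly to full strength", {
  p <- catchment_parameters()
  g <- std_grid()
  ids <- c("awareness_campaign", "social_connectedness")
  before <- apply_interventions(p, ids, 519, g)
  expect_equal(unclass(before)[param_names_flat()[1:10]],
               unclass(p)[param_names_flat()[1:10]])
  expect_equal(param_vector(before), param_vector(p))
  # half-way through the 13-week ramp: half the multiplicative distance
  mid <- apply_interventions(p, ids, 520 + 6.5, g)
  expect_equal(mid$help_seeking_rate,
               p$help_seeking_rate * (1 + (1.30 - 1) * 0.5))
  after <- apply_interventions(p, ids, 520 + 13, g)
  expect_equal(after$help_seeking_rate, p$help_seeking_rate * 1.30)
  expect_equal(after$distress_onset_rate, p$distress_onset_rate * 0.93)
})

test_that("multiplicative effects compose commutatively", {
  p <- catchment_parameters()
  g <- std_grid()
  a <- intervention("a", "A", list(list(path = "distress_onset_rate",
                                        mode = "multiply", magnitude = 0.8)),
                    ramp_weeks = 0)
  b <- intervention("b", "B", list(list(path = "distress_onset_rate",
                                        mode = "multiply", magnitude = 0.9)),
                    ramp_weeks = 0)
  eff_ab <- prepare_effects(list(a, b), p, g)
  eff_ba <- prepare_effects(list(b, a), p, g)
  v0 <- param_vector(p)
  vab <- effective_param_vector(v0, eff_ab, 600)
  vba <- effective_param_vector(v0, eff_ba, 600)
  expect_equal(vab, vba)
  expect_equal(vab[["distress_onset_rate"]],
               p$distress_onset_rate * 0.72)
})

test_that("two replace effects on one path are a configuration conflict", {
  p <- catchment_parameters()
  g <- std_grid()
  a <- intervention("a", "A", list(list(path = "waiting_tolerance",
                                        mode = "replace", magnitude = 6)))
  b <- intervention("b", "B", list(list(path = "waiting_tolerance",
                                        mode = "replace", magnitude = 8)))
  expect_error(prepare_effects(list(a, b), p, g), "replace-target")
  expect_silent(prepare_effects(list(a), p, g))
})

test_that("safety planning bites harder where ED presentation rates are higher", {
  g <- std_grid(); w <- std_window()
  lo <- catchment_parameters("lo_ed", initial_population = 4e5,
                             ed_presentation_rate = 0.004)
  hi <- catchment_parameters("hi_ed", initial_population = 4e5,
                             ed_presentation_rate = 0.008)
  r_lo <- run_scenario(lo, "safety_planning", g, w)
  r_hi <- run_scenario(hi, "safety_planning", g, w)
  expect_gt(r_hi$pct_reduction, r_lo$pct_reduction)
})

test_that("combined interventions are not additive somewhere in the synthetic state", {
  g <- std_grid(); w <- std_window()
  pair <- c("awareness_campaign", "care_coordination")
  nonadd <- vapply(synthetic_state()[c(1, 9, 10)], function(p) {
    snap <- catchment_snapshot(p, g, w)
    b <- run_baseline(p, g, w, snapshot = snap)
    r1 <- run_scenario(p, pair[1], g, w, snapshot = snap, baseline = b)
    r2 <- run_scenario(p, pair[2], g, w, snapshot = snap, baseline = b)
    r12 <- run_scenario(p, pair, g, w, snapshot = snap, baseline = b)
    abs(r12$reduction - (r1$reduction + r2$reduction)) /
      b$cumulative_suicides
  }, numeric(1))
  expect_gt(max(nonadd), 0.01)
})
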