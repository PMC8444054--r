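# Shared fixtures, built once per test run.

std_grid <- function() time_grid("2011-01-01", 20, 8)
std_window <- function() forecast_window("2021-01-01", "2031-01-01")

# The synthetic ten-catchment state under the default generator seed; cached
# because several files use it.
.fixture_env <- new.env(parent = emptyenv())
synthetic_state <- function() {
  if (is.null(.fixture_env$state)) .fixture_env$state <- generate_state(20211)
  .fixture_env$state
}

# A quiet catchment with every dynamic process switched off: nothing moves.
inert_parameters <- function(pop = 1e5) {
  catchment_parameters(
    "inert", initial_population = pop,
    birth_rate = 0, migration_rate = 0, background_mortality = 0,
    distress_onset_rate = 0, distress_recovery_untreated = 0,
    distress_recovery_in_care = 0, help_seeking_rate = 0,
    ed_presentation_rate = 0,
    attempt_rate_distressed_untreated = 0, attempt_rate_in_care = 0,
    attempt_rate_postdischarge = 0,
    capacity_growth = list(gp = 0, specialist = 0, cmhc = 0, inpatient = 0,
                           online = 0)
  )
}

# Two-state distress chain: demography, services and suicidal behaviour off,
# only onset/recovery active.
two_state_parameters <- function(onset, recovery, pop = 1e5, prev0 = 0.5) {
  catchment_parameters(
    "two_state", initial_population = pop,
    initial_distress_prevalence = prev0,
    birth_rate = 0, migration_rate = 0, background_mortality = 0,
    distress_onset_rate = onset, distress_recovery_untreated = recovery,
    help_seeking_rate = 0, ed_presentation_rate = 0,
    attempt_rate_distressed_untreated = 0, attempt_rate_in_care = 0,
    attempt_rate_postdischarge = 0,
    capacity_growth = list(gp = 0, specialist = 0, cmhc = 0, inpatient = 0,
                           online = 0)
  )
}

# A three-entry toy catalogue whose members specialise by catchment type:
# a reach-scaled risk cut (strong where ED presentation rates are high), a
# uniform aftercare effect, and primary-care capacity relief (strong where
# the GP queue is starved).
toy_catalogue <- function() {
  list(
    X = intervention("X", "reach-scaled risk reduction", list(
      list(path = "attempt_rate_distressed_untreated", mode = "multiply",
           magnitude = 0.88, reach_param = "ed_presentation_rate",
           reach_ref = 0.0085, reach_cap = 2))),
    Y = intervention("Y", "aftercare risk reduction", list(
      list(path = "attempt_rate_postdischarge", mode = "multiply",
           magnitude = 0.45))),
    Z = intervention("Z", "primary-care capacity relief", list(
      list(path = "capacity_growth.gp", mode = "add", magnitude = 0.12)))
  )
}

toy_catchment_A <- function() {
  catchment_parameters("A", initial_population = 4e5,
                       ed_presentation_rate = 0.009)
}
toy_catchment_B <- function() {
  catchment_parameters("B", initial_population = 4e5,
                       ed_presentation_rate = 8e-4,
                       gp_capacity = 0.0024 * 4e5)
}
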