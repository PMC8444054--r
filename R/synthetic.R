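#' Generate a synthetic state of heterogeneous catchments
#'
#' Produces `n_catchments` parameter sets emulating the regional
#' heterogeneity of a populous Australian state commissioned through ten
#' PHN-like catchments: populations spanning roughly 243 000 to 1.57
#' million, mean yearly suicide rates spanning roughly 7.61--12.18 per
#' 100 000, and strongly varying emergency department presentation rates and
#' service capacity margins. Remote catchments get high ED presentation
#' multipliers (1.5--2.0) and thin capacity (slack 0.7--0.9); metropolitan
#' catchments get generous capacity (slack 1.2--1.5). These profile ranges
#' are generator defaults describing a plausible state, not claims about any
#' real jurisdiction.
#'
#' For each catchment an inner bisection scales the suicidal-behaviour risk
#' rates jointly until the business-as-usual mean yearly suicide rate over
#' the first ten model years is within 10% of the profile's target rate; a
#' profile that cannot be matched raises an error naming it.
#'
#' Deterministic given `seed`; the global RNG state is restored.
#'
#' @param seed integer seed.
#' @param n_catchments number of catchments (default 10).
#' @param engine integration engine used during rate matching.
#' @return List of `n_catchments` [catchment_parameters()] objects, with the
#'   generating profile attached as attribute `"profile"`.
#' @export
generate_state <- function(seed = 20211, n_catchments = 10, engine = "cpp") {
  stopifnot(n_catchments >= 1)
  profiles <- with_seed(seed, synth_profiles(n_catchments))
  out <- vector("list", n_catchments)
  for (i in seq_len(n_catchments)) {
    out[[i]] <- profile_to_parameters(profiles[[i]], engine = engine)
  }
  out
}

# Draw the profile table: population, density class, disadvantage, target
# suicide rate, ED multiplier, capacity slack. Classes are assigned so the
# state always contains both metro slack and remote scarcity.
synth_profiles <- function(n) {
  classes <- rep(c("metro", "regional", "remote"),
                 c(ceiling(0.4 * n), ceiling(0.4 * n), n))[1:n]
  # populations: log-spaced over the target range, largest in metro
  pop <- exp(seq(log(1.57e6), log(2.43e5), length.out = n))
  pop <- pop * stats::runif(n, 0.97, 1.03)
  pop <- pmin(pmax(pop, 2.43e5), 1.57e6)
  # target mean yearly suicide rates rise with remoteness/disadvantage
  rate <- seq(7.61, 12.18, length.out = n) + stats::runif(n, -0.25, 0.25)
  rate <- pmin(pmax(rate, 7.61), 12.18)
  disadvantage <- seq(-1.2, 1.4, length.out = n) + stats::runif(n, -0.2, 0.2)
  lapply(seq_len(n), function(i) {
    cl <- classes[i]
    ed_mult <- switch(cl,
      metro = stats::runif(1, 0.8, 1.1),
      regional = stats::runif(1, 1.0, 1.4),
      remote = stats::runif(1, 1.5, 2.0))
    slack <- switch(cl,
      metro = stats::runif(1, 1.2, 1.5),
      regional = stats::runif(1, 0.9, 1.2),
      remote = stats::runif(1, 0.60, 0.80))
    # specialist services are demand-saturated in the cities and (relative to
    # their small referral streams) less binding in the bush, where the
    # primary-care queue is the bottleneck
    spec_slack <- switch(cl,
      metro = stats::runif(1, 0.32, 0.42),
      regional = stats::runif(1, 1.0, 1.2),
      remote = stats::runif(1, 1.1, 1.3))
    growth <- switch(cl,
      metro = stats::runif(1, 0.02, 0.03),
      regional = stats::runif(1, 0.01, 0.02),
      remote = stats::runif(1, 0.005, 0.015))
    # city psychiatrist/allied capacity grows slower than demand; elsewhere
    # the (small) specialist stream keeps pace
    spec_growth <- if (cl == "metro") stats::runif(1, 0.006, 0.010) else
      growth * 1.25
    list(name = sprintf("synthetic_%02d_%s", i, cl),
         population = pop[i], density_class = cl,
         disadvantage_index = disadvantage[i],
         target_suicide_rate = rate[i],
         ed_presentation_multiplier = ed_mult,
         capacity_slack = slack,
         specialist_slack = spec_slack,
         capacity_growth = growth,
         specialist_growth = spec_growth)
  })
}

# Map a profile to a full parameter set and match the target suicide rate.
profile_to_parameters <- function(profile, engine = "cpp") {
  P <- profile$population
  prev <- 0.28 + 0.02 * profile$disadvantage_index / 1.5
  p <- catchment_parameters(
    name = profile$name,
    initial_population = P,
    initial_distress_prevalence = prev,
    ed_presentation_rate = 0.004 * profile$ed_presentation_multiplier,
    gp_capacity = 0.004 * P * profile$capacity_slack,
    specialist_capacity = 0.001 * P * profile$specialist_slack,
    cmhc_capacity = 0.00045 * P * profile$capacity_slack,
    inpatient_capacity = 0.0005 * P * profile$capacity_slack,
    capacity_growth = list(
      gp = profile$capacity_growth,
      specialist = profile$specialist_growth,
      cmhc = profile$capacity_growth,
      inpatient = profile$capacity_growth * 0.5
    )
  )
  p <- match_suicide_rate(p, profile$target_suicide_rate, engine = engine)
  attr(p, "profile") <- profile
  p
}

# Jointly scale the three attempt rates by bisection until the baseline mean
# yearly suicide rate over the first 10 model years hits the target.
match_suicide_rate <- function(p, target, tol = 0.02, engine = "cpp",
                               max_iter = 50) {
  base <- c(p$attempt_rate_distressed_untreated, p$attempt_rate_in_care,
            p$attempt_rate_postdischarge)
  grid10 <- time_grid("2011-01-01", 10, 8)
  rate_at <- function(theta) {
    q <- p
    q$attempt_rate_distressed_untreated <- base[1] * theta
    q$attempt_rate_in_care <- base[2] * theta
    q$attempt_rate_postdischarge <- base[3] * theta
    ym <- yearly_metrics(simulate_catchment(q, grid10, engine = engine))
    mean(ym$suicide_rate_per_1e5)
  }
  lo <- 0.1; hi <- 5
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (target < r_lo || target > r_hi) {
    stop(sprintf(
      "cannot match target suicide rate %.2f for profile '%s' (achievable %.2f-%.2f)",
      target, p$name, r_lo, r_hi), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target) / target < tol) break
    if (r < target) lo <- mid else hi <- mid
  }
  if (abs(r - target) / target >= 0.10) {
    stop(sprintf("bisection failed to match suicide rate for profile '%s'",
                 p$name), call. = FALSE)
  }
  p$attempt_rate_distressed_untreated <- base[1] * mid
  p$attempt_rate_in_care <- base[2] * mid
  p$attempt_rate_postdischarge <- base[3] * mid
  validate_parameters(p)
}

#' Generate synthetic observed yearly series for calibration
#'
#' Runs the model over the historical window under the given (true)
#' parameters, extracts the yearly calibration metrics (distress prevalence,
#' self-harm hospitalisations, suicides, ED presentations and service
#' usage), and applies independent multiplicative lognormal noise with the
#' requested coefficient of variation (lognormal noise keeps all values
#' positive, as the MAPE objective requires). With `noise_cv = 0` the series
#' equal the model outputs exactly.
#'
#' @param p a [catchment_parameters()] object (the true parameters).
#' @param years calendar years to report (default 2011--2020).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed (used only when `noise_cv > 0`).
#' @param engine integration engine.
#' @return A `data.frame` with columns `metric`, `year`, `value`.
#' @export
generate_observed_series <- function(p, years = 2011:2020, noise_cv = 0,
                                     seed = 1, engine = "cpp") {
  stopifnot(noise_cv >= 0)
  horizon <- max(years) - min(years) + 1L
  grid <- time_grid(sprintf("%d-01-01", min(years)), horizon, 8)
  ym <- yearly_metrics(simulate_catchment(p, grid, engine = engine))
  metrics <- c("mean_prevalence", "selfharm_hospitalisations", "suicides",
               "ed_presentations", "gp_episodes", "specialist_episodes",
               "cmhc_admissions", "inpatient_admissions")
  ym <- ym[ym$year %in% years, , drop = FALSE]
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m, year = ym$year, value = ym[[m]],
               stringsAsFactors = FALSE)
  }))
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    noise <- with_seed(seed,
      exp(stats::rnorm(nrow(out), -sigma^2 / 2, sigma)))
    out$value <- out$value * noise
  }
  rownames(out) <- NULL
  out
}
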