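#' Stock set of the catchment model
#'
#' The model's stocks in their fixed declaration order. Person stocks (the
#' first 11) partition the living catchment population; `TotalPopulation` is
#' an exactly co-integrated closure check; capacity stocks carry per-service
#' throughput (persons/week, or beds for inpatient care); `Cum*` stocks count
#' events cumulatively and are non-decreasing.
#'
#' @return Character vector of 25 stock names.
#' @export
stock_names <- function() {
  c("LowDistress", "DistressedNotInCare", "WaitingGP", "InGPCare",
    "WaitingSpecialist", "InSpecialistCare", "InCMHC", "InInpatient",
    "InOnline", "PostDischarge", "Disengaged",
    "TotalPopulation",
    "CapGP", "CapSpecialist", "CapCMHC", "CapInpatient", "CapOnline",
    "CumSuicides", "CumSelfHarmHosp", "CumEDPresentations",
    "CumGPEpisodes", "CumSpecialistEpisodes", "CumCMHCAdmissions",
    "CumInpatientAdmissions", "CumDisengagements")
}

#' Names of the person (living population) stocks
#' @return Character vector of 11 stock names.
#' @export
person_stocks <- function() stock_names()[1:11]

#' Initial model state for a catchment
#'
#' Distributes the initial population between the low-distress and
#' distressed-not-in-care stocks according to the initial distress
#' prevalence; service stocks start empty (the 2011--2021 lead-in period
#' lets the service system settle before the forecast window opens).
#'
#' @param p a [catchment_parameters()] object.
#' @return Named numeric vector over [stock_names()].
#' @export
initial_model_state <- function(p) {
  s <- stats::setNames(numeric(25), stock_names())
  P <- p$initial_population
  s["LowDistress"] <- (1 - p$initial_distress_prevalence) * P
  s["DistressedNotInCare"] <- p$initial_distress_prevalence * P
  s["TotalPopulation"] <- P
  s["CapGP"] <- p$gp_capacity
  s["CapSpecialist"] <- p$specialist_capacity
  s["CapCMHC"] <- p$cmhc_capacity
  s["CapInpatient"] <- p$inpatient_capacity
  s["CapOnline"] <- p$online_capacity
  s
}

#' Expected waiting time of a service queue
#'
#' First-come-first-served expectation at the current throughput:
#' `queue / capacity` weeks, capped at `cap` to avoid blow-ups when capacity
#' is (near) zero.
#'
#' @param queue persons waiting.
#' @param capacity service throughput, persons/week.
#' @param cap maximum reported waiting time, weeks (default 52).
#' @return Waiting time in weeks.
#' @examples
#' waiting_time(100, 50)  # 2
#' @export
waiting_time <- function(queue, capacity, cap = 52) {
  ifelse(capacity <= 0, cap, pmin(queue / capacity, cap))
}

# Net per-week rates for all 25 stocks given the state vector `s` (canonical
# order) and the *effective* flat parameter vector `v` (param_names_flat()
# order). This is the reference implementation; src/sim_core.cpp mirrors it
# operation for operation.
core_rates_vec <- function(s, v) {
  r <- numeric(25)
  P <- sum(s[1:11])

  # population sector: births into LowDistress, proportional net migration,
  # proportional background mortality
  r[1] <- r[1] + v[2] * P
  mig <- v[3] * s[1:11]
  mort <- v[4] * s[1:11]
  r[1:11] <- r[1:11] + mig - mort

  # distress sector
  onset <- v[6] * s[1]
  r[1] <- r[1] - onset; r[2] <- r[2] + onset
  recu <- v[7] * s[2]
  r[2] <- r[2] - recu; r[1] <- r[1] + recu
  # patients waiting for care can still remit spontaneously
  for (i in c(3L, 5L)) {
    f <- v[7] * s[i]
    r[i] <- r[i] - f; r[1] <- r[1] + f
  }
  # disengaged patients remit more slowly (alienation after poor service
  # experience) — the channel that makes demand-generating campaigns harmful
  # where capacity is scarce
  recd <- v[7] * v[46] * s[11]
  r[11] <- r[11] - recd; r[1] <- r[1] + recd
  for (i in c(4L, 6L, 7L, 8L, 9L)) {
    f <- v[8] * s[i]
    r[i] <- r[i] - f; r[1] <- r[1] + f
  }
  pdout <- s[10] / v[44]
  r[10] <- r[10] - pdout
  r[1] <- r[1] + v[45] * pdout
  r[2] <- r[2] + (1 - v[45]) * pdout

  # services sector: help-seeking and re-seeking
  seek <- v[9] * s[2]
  r[2] <- r[2] - seek
  r[9] <- r[9] + v[10] * seek
  r[3] <- r[3] + (1 - v[10]) * seek
  reseek <- v[9] * v[11] * s[11]
  r[11] <- r[11] - reseek; r[3] <- r[3] + reseek

  # GP queue -> GP care, capacity-limited intake
  gp_in <- min(s[3] / v[34], s[13])
  r[3] <- r[3] - gp_in; r[4] <- r[4] + gp_in; r[21] <- r[21] + gp_in

  # GP episode completion splits by referral fractions
  gp_out <- s[4] / v[29]
  r[4] <- r[4] - gp_out
  r[5] <- r[5] + v[23] * gp_out
  cmhc_want <- v[24] * gp_out
  cmhc_adm <- min(cmhc_want, s[15])
  r[7] <- r[7] + cmhc_adm; r[2] <- r[2] + (cmhc_want - cmhc_adm)
  r[23] <- r[23] + cmhc_adm
  inpt_want <- v[25] * gp_out
  inpt_free <- max(0, (s[16] - s[8]) / v[34])
  inpt_adm <- min(inpt_want, inpt_free)
  r[8] <- r[8] + inpt_adm; r[2] <- r[2] + (inpt_want - inpt_adm)
  r[24] <- r[24] + inpt_adm
  r[9] <- r[9] + v[26] * gp_out
  dis <- v[27] * gp_out
  r[1] <- r[1] + v[28] * dis
  r[2] <- r[2] + (1 - v[28]) * dis

  # specialist queue -> specialist care
  sp_in <- min(s[5] / v[34], s[14])
  r[5] <- r[5] - sp_in; r[6] <- r[6] + sp_in; r[22] <- r[22] + sp_in

  # care episode completions
  sp_out <- s[6] / v[30]
  r[6] <- r[6] - sp_out
  r[1] <- r[1] + v[28] * sp_out; r[2] <- r[2] + (1 - v[28]) * sp_out
  cm_out <- s[7] / v[31]
  r[7] <- r[7] - cm_out
  r[1] <- r[1] + v[28] * cm_out; r[2] <- r[2] + (1 - v[28]) * cm_out
  on_out <- s[9] / v[32]
  r[9] <- r[9] - on_out
  r[1] <- r[1] + v[28] * on_out; r[2] <- r[2] + (1 - v[28]) * on_out
  ip_out <- s[8] / v[33]
  r[8] <- r[8] - ip_out; r[10] <- r[10] + ip_out

  # waiting-time-driven disengagement plus in-care dissatisfaction
  w_gp <- if (s[13] <= 0) v[38] else min(s[3] / s[13], v[38])
  w_sp <- if (s[14] <= 0) v[38] else min(s[5] / s[14], v[38])
  dg <- s[3] * v[36] * w_gp / (w_gp + v[35])
  ds <- s[5] * v[36] * w_sp / (w_sp + v[35])
  r[3] <- r[3] - dg; r[5] <- r[5] - ds
  r[11] <- r[11] + dg + ds
  r[25] <- r[25] + dg + ds
  for (i in c(4L, 6L, 7L, 9L)) {
    f <- v[37] * s[i]
    r[i] <- r[i] - f; r[11] <- r[11] + f
    r[25] <- r[25] + f
  }

  # suicidal behaviour sector
  grate <- c(0, v[39], v[39], v[40], v[39], v[40], v[40], v[40], v[40],
             v[41], v[39])
  for (i in 1:11) {
    if (grate[i] <= 0) next
    att <- grate[i] * s[i]
    deaths <- v[43] * att
    r[i] <- r[i] - deaths
    r[18] <- r[18] + deaths
    hosp_move <- v[42] * (1 - v[43]) * att
    if (i != 8L) {
      r[i] <- r[i] - hosp_move
      r[8] <- r[8] + hosp_move
      r[24] <- r[24] + hosp_move
    }
    r[19] <- r[19] + v[42] * att
  }
  r[20] <- r[20] + v[12] * (s[2] + s[3] + s[5] + s[10] + s[11])

  # capacity stocks grow continuously at their yearly rates
  r[13] <- v[18] / 52 * s[13]
  r[14] <- v[19] / 52 * s[14]
  r[15] <- v[20] / 52 * s[15]
  r[16] <- v[21] / 52 * s[16]
  r[17] <- v[22] / 52 * s[17]

  # exact closure: the population tally integrates the same net person flows
  r[12] <- sum(r[1:11])
  r
}

core_aux_vec <- function(s, v) {
  P <- sum(s[1:11])
  c(
    prevalence = if (P > 0) (P - s[1]) / P else 0,
    wait_gp = if (s[13] <= 0) v[38] else min(s[3] / s[13], v[38]),
    wait_specialist = if (s[14] <= 0) v[38] else min(s[5] / s[14], v[38])
  )
}

#' Flow evaluator for the generic engine
#'
#' Wraps the catchment model's flow equations (optionally under a set of
#' interventions) as a `flows(state, t)` closure usable with [euler_step()]
#' and [integrate_model()].
#'
#' @param p a [catchment_parameters()] object.
#' @param effects an effects table from [prepare_effects()], or `NULL` for
#'   business as usual.
#' @return A function `(state, t) -> named rates`.
#' @export
core_flows <- function(p, effects = NULL) {
  v0 <- param_vector(p)
  nm <- stock_names()
  function(state, t) {
    v <- effective_param_vector(v0, effects, t)
    stats::setNames(core_rates_vec(as.numeric(state[nm]), v), nm)
  }
}

core_aux <- function(p, effects = NULL) {
  v0 <- param_vector(p)
  nm <- stock_names()
  function(state, t) {
    v <- effective_param_vector(v0, effects, t)
    core_aux_vec(as.numeric(state[nm]), v)
  }
}

#' Simulate one catchment over (part of) the grid
#'
#' Integrates the catchment model with the explicit-Euler engine. The
#' compiled path (`engine = "cpp"`) and the pure-R reference path
#' (`engine = "r"`) implement identical equations; the compiled path exists
#' because the exhaustive combination search needs tens of thousands of runs.
#'
#' @param p a [catchment_parameters()] object.
#' @param grid a [time_grid()].
#' @param interventions an `intervention_set` (or character vector of ids),
#'   or `NULL` for the business-as-usual baseline.
#' @param catalogue the intervention catalogue (default [default_catalogue()]).
#' @param engine `"cpp"` (default) or `"r"`.
#' @param from_year start the integration this many model years into the
#'   grid (state must then be supplied via `state0`).
#' @param state0 optional starting state (named vector over [stock_names()]);
#'   defaults to [initial_model_state()] when `from_year = 0`.
#' @return A `trajectory` whose `times` are absolute model weeks on `grid`.
#' @export
simulate_catchment <- function(p, grid, interventions = NULL,
                               catalogue = default_catalogue(),
                               engine = c("cpp", "r"),
                               from_year = 0, state0 = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(grid, "time_grid"))
  if (from_year < 0 || from_year >= grid$horizon_years) {
    stop("`from_year` outside the grid horizon", call. = FALSE)
  }
  if (from_year > 0 && is.null(state0)) {
    stop("`state0` must be supplied when starting mid-grid", call. = FALSE)
  }
  if (is.null(state0)) state0 <- initial_model_state(p)
  state0 <- state0[stock_names()]
  effects <- prepare_effects(interventions, p, grid, catalogue)
  t0 <- 52 * from_year
  n_sub <- (grid$horizon_years - from_year) * 52L * grid$steps_per_week

  if (engine == "cpp") {
    out <- sim_core_cpp(param_vector(p), as.numeric(state0), n_sub,
                        grid$dt_weeks, t0,
                        if (is.null(effects)) matrix(0, 0, 5) else effects)
    if (out$n_clamped > 0) {
      warning(sprintf("%d stock value(s) clamped at zero during integration",
                      out$n_clamped), call. = FALSE)
    }
    states <- out$states
    colnames(states) <- stock_names()
    aux <- out$aux
    colnames(aux) <- c("prevalence", "wait_gp", "wait_specialist")
    traj <- new_trajectory(grid, t0 + seq(0, by = grid$dt_weeks,
                                          length.out = n_sub + 1),
                           states, aux)
  } else {
    sub <- grid
    sub$horizon_years <- grid$horizon_years - as.integer(from_year)
    sub$horizon_weeks <- sub$horizon_years * 52L
    sub$n_steps <- n_sub
    flows <- core_flows(p, effects)
    auxf <- core_aux(p, effects)
    traj <- integrate_model(
      state0,
      function(state, t) flows(state, t + t0),
      sub,
      function(state, t) auxf(state, t + t0)
    )
    traj$grid <- grid
    traj$times <- traj$times + t0
  }
  traj$catchment <- p$name
  traj
}

#' Yearly output metrics from a trajectory
#'
#' Differences the cumulative event stocks over 52-week model years and
#' averages the auxiliary series within each year, producing the model's
#' reporting metrics: suicides, self-harm hospitalisations, emergency
#' department presentations, GP / specialist / community mental health /
#' inpatient activity, disengagements, mean distress prevalence, mean
#' waiting times, mean population and the yearly suicide rate per 100 000.
#'
#' @param traj a `trajectory` from [simulate_catchment()].
#' @return A `data.frame`, one row per complete model year, with a `year`
#'   column giving the calendar year in which the model year starts.
#' @export
yearly_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  spw <- traj$grid$steps_per_week
  steps_year <- 52L * spw
  n <- nrow(traj$states) - 1L
  n_years <- n %/% steps_year
  if (n_years < 1) stop("trajectory covers less than one model year",
                        call. = FALSE)
  if (n %% steps_year != 0) {
    warning("partial final model year excluded from yearly metrics",
            call. = FALSE)
  }
  bounds <- seq(1L, by = steps_year, length.out = n_years + 1L)
  cum_metrics <- c(
    suicides = "CumSuicides", selfharm_hospitalisations = "CumSelfHarmHosp",
    ed_presentations = "CumEDPresentations", gp_episodes = "CumGPEpisodes",
    specialist_episodes = "CumSpecialistEpisodes",
    cmhc_admissions = "CumCMHCAdmissions",
    inpatient_admissions = "CumInpatientAdmissions",
    disengagements = "CumDisengagements"
  )
  year0 <- as.integer(format(traj$grid$start_date, "%Y")) +
    as.integer(round(traj$times[1] / 52))
  out <- data.frame(year = year0 + seq_len(n_years) - 1L)
  for (m in names(cum_metrics)) {
    series <- traj$states[, cum_metrics[[m]]]
    out[[m]] <- diff(series[bounds])
  }
  pop <- rowSums(traj$states[, person_stocks(), drop = FALSE])
  mean_in_year <- function(x) {
    vapply(seq_len(n_years), function(y) {
      mean(x[bounds[y]:bounds[y + 1L]])
    }, numeric(1))
  }
  out$mean_population <- mean_in_year(pop)
  out$mean_prevalence <- mean_in_year(traj$aux[, "prevalence"])
  out$mean_wait_gp <- mean_in_year(traj$aux[, "wait_gp"])
  out$mean_wait_specialist <- mean_in_year(traj$aux[, "wait_specialist"])
  out$suicide_rate_per_1e5 <- 1e5 * out$suicides / out$mean_population
  out
}
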