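#' Catchment parameterisation
#'
#' The complete numeric description of one service catchment: demography,
#' psychological distress dynamics, mental health service capacities and
#' pathway fractions, queueing/disengagement behaviour, and suicidal
#' behaviour risk. All rates are per week unless stated otherwise; capacity
#' growth rates are fractions per (52-week) model year; durations and windows
#' are in weeks. The defaults describe a mid-size, moderately resourced
#' catchment; [generate_state()] produces heterogeneous variants spanning a
#' realistic regional range.
#'
#' Parameter groups:
#' \describe{
#'   \item{demography}{`initial_population`, `birth_rate`, `migration_rate`
#'     (net, may be negative), `background_mortality` — per-capita weekly
#'     rates.}
#'   \item{distress}{`initial_distress_prevalence` (fraction of the population
#'     with moderate-to-very-high distress, Kessler-10 score 16--50),
#'     `distress_onset_rate` (low-distress -> distressed),
#'     `distress_recovery_untreated`, `distress_recovery_in_care`.}
#'   \item{services}{`help_seeking_rate` (distressed-not-in-care -> primary
#'     care queue), `direct_online_fraction` (help-seekers going straight to
#'     online services), `reseek_multiplier` (relative help-seeking rate of
#'     previously disengaged patients), `ed_presentation_rate` (mental
#'     health-related emergency department presentations per distressed
#'     person per week), per-service capacities (`gp_capacity`,
#'     `specialist_capacity`, `cmhc_capacity` in persons/week;
#'     `inpatient_capacity` in beds; `online_capacity` effectively
#'     unconstrained), `capacity_growth` (per service, /year),
#'     `referral_fractions` (split of completed GP episodes; must sum to 1),
#'     `discharge_recovered_fraction`, `care_duration` (mean in-care
#'     residence, weeks), `admission_lag` (weeks), `waiting_tolerance`
#'     (weeks; scale of the waiting-time disengagement response),
#'     `disengagement_max` (/week, saturating maximum),
#'     `dissatisfaction_rate` (/week from in-care stocks),
#'     `waiting_time_cap` (weeks).}
#'   \item{suicidal behaviour}{`attempt_rate_distressed_untreated`,
#'     `attempt_rate_in_care`, `attempt_rate_postdischarge` (/week),
#'     `hospitalisation_fraction` (of attempts), `case_fatality` (fraction of
#'     attempts that are fatal), `postdischarge_window` (weeks),
#'     `postdischarge_recovered_fraction`.}
#' }
#'
#' @param name catchment label.
#' @param ... named overrides of any default, using either top-level names
#'   (e.g. `help_seeking_rate = 0.03`) or nested lists (`capacity_growth =
#'   list(gp = 0.03)` merges into the default group).
#' @return A validated object of class `catchment_parameters`.
#' @examples
#' p <- catchment_parameters("demo", initial_population = 5e5)
#' p$referral_fractions$specialist
#' @export
catchment_parameters <- function(name = "catchment", ...) {
  p <- default_parameters()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(over)) {
      if (is.list(p[[nm]])) {
        badsub <- setdiff(names(over[[nm]]), names(p[[nm]]))
        if (length(badsub)) {
          stop(sprintf("unknown field(s) in `%s`: %s", nm,
                       paste(badsub, collapse = ", ")), call. = FALSE)
        }
        p[[nm]][names(over[[nm]])] <- over[[nm]]
      } else {
        p[[nm]] <- over[[nm]]
      }
    }
  }
  p$name <- as.character(name)
  validate_parameters(structure(p, class = "catchment_parameters"))
}

default_parameters <- function() {
  list(
    name = "catchment",
    initial_population = 8e5,
    birth_rate = 0.00025,
    migration_rate = 0.00012,
    background_mortality = 0.00013,
    initial_distress_prevalence = 0.28,
    distress_onset_rate = 0.015,
    distress_recovery_untreated = 0.0385,
    distress_recovery_in_care = 0.077,
    help_seeking_rate = 0.02,
    direct_online_fraction = 0.15,
    reseek_multiplier = 0.3,
    ed_presentation_rate = 0.004,
    gp_capacity = 0.004 * 8e5,
    specialist_capacity = 0.001 * 8e5,
    cmhc_capacity = 0.0006 * 8e5,
    inpatient_capacity = 0.0005 * 8e5,
    online_capacity = 1e9,
    capacity_growth = list(gp = 0.02, specialist = 0.025, cmhc = 0.02,
                           inpatient = 0.01, online = 0),
    referral_fractions = list(specialist = 0.25, cmhc = 0.15,
                              inpatient = 0.05, online = 0.10,
                              discharge = 0.45),
    discharge_recovered_fraction = 0.5,
    care_duration = list(gp = 4, specialist = 12, cmhc = 12, online = 8,
                         inpatient = 2),
    admission_lag = 1,
    waiting_tolerance = 4,
    disengagement_max = 0.25,
    dissatisfaction_rate = 0.02,
    waiting_time_cap = 52,
    attempt_rate_distressed_untreated = 6e-4,
    attempt_rate_in_care = 2.4e-4,
    attempt_rate_postdischarge = 1.2e-2,
    hospitalisation_fraction = 0.3,
    case_fatality = 0.015,
    postdischarge_window = 13,
    postdischarge_recovered_fraction = 0.4,
    disengaged_recovery_multiplier = 0.15
  )
}

#' Validate a catchment parameter set
#'
#' Checks non-negativity of all rates, that all fractions lie in `[0, 1]`,
#' that referral fractions sum to 1, and that care is protective
#' (`attempt_rate_in_care <= attempt_rate_distressed_untreated`). Errors name
#' the offending field.
#'
#' @param p a `catchment_parameters` object (or plain list with the same
#'   fields).
#' @return `p`, invisibly classed, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  paths <- param_names_flat()
  vals <- vapply(paths, function(pt) param_get(p, pt), numeric(1))
  names(vals) <- paths
  if (any(!is.finite(vals) & !grepl("online_capacity", names(vals)))) {
    stop("non-finite parameter value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  neg <- names(vals)[vals < 0 & names(vals) != "migration_rate"]
  if (length(neg)) {
    stop("negative parameter value(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  fracs <- c("initial_distress_prevalence", "direct_online_fraction",
             "discharge_recovered_fraction", "hospitalisation_fraction",
             "case_fatality", "postdischarge_recovered_fraction",
             paste0("referral_fractions.",
                    c("specialist", "cmhc", "inpatient", "online", "discharge")))
  badf <- fracs[vals[fracs] < 0 | vals[fracs] > 1]
  if (length(badf)) {
    stop("fraction(s) outside [0, 1]: ", paste(badf, collapse = ", "),
         call. = FALSE)
  }
  rf <- sum(unlist(p$referral_fractions))
  if (abs(rf - 1) > 1e-8) {
    stop(sprintf("referral_fractions must sum to 1 (got %.6f)", rf),
         call. = FALSE)
  }
  if (p$attempt_rate_in_care > p$attempt_rate_distressed_untreated) {
    stop("attempt_rate_in_care exceeds attempt_rate_distressed_untreated; ",
         "care must be protective in this parameterisation", call. = FALSE)
  }
  if (p$initial_population <= 0) {
    stop("initial_population must be positive", call. = FALSE)
  }
  invisible(structure(p, class = "catchment_parameters"))
}

#' @export
print.catchment_parameters <- function(x, ...) {
  cat(sprintf(
    "<catchment_parameters> '%s': population %s, distress prevalence %.1f%%, GP capacity %.0f/wk\n",
    x$name, format(x$initial_population, big.mark = ","),
    100 * x$initial_distress_prevalence, x$gp_capacity
  ))
  invisible(x)
}

# Canonical flat parameter paths, in the fixed order shared with the compiled
# integrator. Nested groups use dotted paths.
param_names_flat <- function() {
  c("initial_population", "birth_rate", "migration_rate",
    "background_mortality", "initial_distress_prevalence",
    "distress_onset_rate", "distress_recovery_untreated",
    "distress_recovery_in_care", "help_seeking_rate",
    "direct_online_fraction", "reseek_multiplier", "ed_presentation_rate",
    "gp_capacity", "specialist_capacity", "cmhc_capacity",
    "inpatient_capacity", "online_capacity",
    "capacity_growth.gp", "capacity_growth.specialist",
    "capacity_growth.cmhc", "capacity_growth.inpatient",
    "capacity_growth.online",
    "referral_fractions.specialist", "referral_fractions.cmhc",
    "referral_fractions.inpatient", "referral_fractions.online",
    "referral_fractions.discharge",
    "discharge_recovered_fraction",
    "care_duration.gp", "care_duration.specialist", "care_duration.cmhc",
    "care_duration.online", "care_duration.inpatient",
    "admission_lag", "waiting_tolerance", "disengagement_max",
    "dissatisfaction_rate", "waiting_time_cap",
    "attempt_rate_distressed_untreated", "attempt_rate_in_care",
    "attempt_rate_postdischarge", "hospitalisation_fraction",
    "case_fatality", "postdischarge_window",
    "postdischarge_recovered_fraction", "disengaged_recovery_multiplier")
}

#' Read a parameter value by dotted path
#'
#' @param p a `catchment_parameters` object.
#' @param path a flat name (`"help_seeking_rate"`) or dotted nested path
#'   (`"capacity_growth.gp"`).
#' @return The numeric value.
#' @export
param_get <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- p
  for (pt in parts) {
    if (is.null(v[[pt]])) stop("unknown parameter path: ", path, call. = FALSE)
    v <- v[[pt]]
  }
  if (!is.numeric(v)) stop("path does not address a numeric value: ", path,
                           call. = FALSE)
  v
}

#' Set a parameter value by dotted path
#'
#' @inheritParams param_get
#' @param value new numeric value.
#' @return The modified (re-validated) parameter set.
#' @export
param_set <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    if (is.null(p[[parts]])) stop("unknown parameter path: ", path,
                                  call. = FALSE)
    p[[parts]] <- value
  } else if (length(parts) == 2) {
    if (is.null(p[[parts[1]]][[parts[2]]])) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    p[[parts[1]]][[parts[2]]] <- value
  } else {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  validate_parameters(p)
}

# Pack a parameter set into the canonical numeric vector used by the
# compiled integrator (names = param_names_flat()).
param_vector <- function(p) {
  paths <- param_names_flat()
  v <- vapply(paths, function(pt) param_get(p, pt), numeric(1))
  names(v) <- paths
  v
}

#' Write a catchment parameter file
#'
#' Serialises a parameter set to a structured YAML config with a schema
#' version tag; [read_catchment_config()] inverts it exactly.
#'
#' @param p a `catchment_parameters` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_catchment_config <- function(p, path) {
  stopifnot(inherits(p, "catchment_parameters"))
  obj <- unclass(p)
  obj <- c(list(schema = "phnsim/catchment/1"), obj)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a catchment parameter file
#'
#' @param path a YAML file written by [write_catchment_config()] (or hand
#'   authored to the same schema).
#' @return A validated `catchment_parameters` object.
#' @export
read_catchment_config <- function(path) {
  if (!file.exists(path)) stop("catchment config not found: ", path,
                               call. = FALSE)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema) || !identical(obj$schema, "phnsim/catchment/1")) {
    stop("not a recognised catchment config (missing/unknown schema tag): ",
         path, call. = FALSE)
  }
  obj$schema <- NULL
  known <- names(default_parameters())
  bad <- setdiff(names(obj), known)
  if (length(bad)) {
    stop("unknown field(s) in catchment config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(known, names(obj))
  if (length(missing)) {
    stop("catchment config missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_parameters(structure(obj, class = "catchment_parameters"))
}
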