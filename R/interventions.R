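#' Define an intervention
#'
#' An intervention is a set of *direct* effects on catchment parameters,
#' switched on at a start date and phased in linearly over a ramp period.
#' All indirect consequences (queueing, disengagement, recovery, mortality)
#' are generated by the model structure, so combined interventions need not
#' act additively.
#'
#' @param id short machine id.
#' @param name display name.
#' @param effects list of effects, each a list with fields `path` (dotted
#'   parameter path), `mode` (`"multiply"`, `"add"` or `"replace"`),
#'   `magnitude`, and optionally `reach_param`, `reach_ref`, `reach_cap` for
#'   effects whose realised strength scales with a catchment characteristic
#'   (e.g. safety planning reach scaling with the emergency department
#'   presentation rate). For a reach-scaled multiplier the realised factor is
#'   `1 - (1 - magnitude) * min(reach_cap, value(reach_param) / reach_ref)`.
#' @param start_date date the intervention begins (default 2021-01-01).
#' @param ramp_weeks weeks from start to full effect (linear ramp,
#'   default 13).
#' @param reconstruction flag marking catalogue entries whose identity is a
#'   reconstruction rather than a published programme name.
#' @return An object of class `intervention`.
#' @export
intervention <- function(id, name, effects, start_date = "2021-01-01",
                         ramp_weeks = 13, reconstruction = FALSE) {
  if (!length(effects)) stop("`effects` must be non-empty", call. = FALSE)
  known_paths <- param_names_flat()
  for (e in effects) {
    if (!all(c("path", "mode", "magnitude") %in% names(e))) {
      stop("each effect needs fields path, mode, magnitude", call. = FALSE)
    }
    if (!e$path %in% known_paths) {
      stop("effect targets unknown parameter path: ", e$path, call. = FALSE)
    }
    if (!e$mode %in% c("multiply", "add", "replace")) {
      stop("effect mode must be multiply, add or replace", call. = FALSE)
    }
    if (e$mode == "multiply" && e$magnitude <= 0) {
      stop("multiply magnitudes must be > 0 (effect on ", e$path, ")",
           call. = FALSE)
    }
  }
  structure(
    list(id = id, name = name, effects = effects,
         start_date = as.Date(start_date), ramp_weeks = ramp_weeks,
         reconstruction = isTRUE(reconstruction)),
    class = "intervention"
  )
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("<intervention> %s (%s): %d effect(s), start %s, ramp %g wk%s\n",
              x$id, x$name, length(x$effects), format(x$start_date),
              x$ramp_weeks,
              if (x$reconstruction) " [reconstruction]" else ""))
  invisible(x)
}

eff <- function(path, mode, magnitude, reach_param = NULL, reach_ref = NULL,
                reach_cap = 2) {
  out <- list(path = path, mode = mode, magnitude = magnitude)
  if (!is.null(reach_param)) {
    out$reach_param <- reach_param
    out$reach_ref <- reach_ref
    out$reach_cap <- reach_cap
  }
  out
}

#' The 13-intervention catalogue
#'
#' The default suicide prevention and mental health services intervention
#' catalogue. Direct-effect magnitudes are calibrated-to-figure defaults:
#' they are chosen so that single-intervention percentage reductions on the
#' synthetic state fall in realistic, heterogeneous ranges (strong and fairly
#' uniform post-attempt care and social-connectedness effects; safety
#' planning whose reach scales with emergency department presentation rates;
#' congestion-sensitive awareness campaigns; capacity-growth interventions
#' that only matter where capacity binds). Three catalogue entries are named
#' reconstructions (`reconstruction = TRUE`): the catalogue size is fixed at
#' 13 but only ten programme identities are published, so the remaining three
#' are plausible placeholders, overridable via [intervention()].
#'
#' @param start_date intervention start date applied to every entry.
#' @param ramp_weeks ramp length applied to every entry.
#' @return Named list of 13 [intervention()] objects.
#' @export
default_catalogue <- function(start_date = "2021-01-01", ramp_weeks = 13) {
  specs <- list(
    intervention("post_attempt_care", "Post-suicide attempt care",
      list(eff("attempt_rate_postdischarge", "multiply", 0.45)),
      start_date, ramp_weeks),
    intervention("safety_planning", "Safety planning in emergency departments",
      list(eff("attempt_rate_distressed_untreated", "multiply", 0.885,
               reach_param = "ed_presentation_rate", reach_ref = 0.0085)),
      start_date, ramp_weeks),
    intervention("care_coordination", "Technology-enabled care coordination",
      list(eff("disengagement_max", "multiply", 0.50),
           eff("dissatisfaction_rate", "multiply", 0.50),
           eff("reseek_multiplier", "multiply", 1.50)),
      start_date, ramp_weeks),
    intervention("family_psychoeducation",
      "Family psychoeducation and support programmes",
      list(eff("distress_onset_rate", "multiply", 0.955),
           eff("help_seeking_rate", "multiply", 1.10)),
      start_date, ramp_weeks),
    intervention("social_connectedness", "Social-connectedness programmes",
      list(eff("distress_onset_rate", "multiply", 0.93)),
      start_date, ramp_weeks),
    intervention("awareness_campaign", "Community awareness campaigns",
      list(eff("help_seeking_rate", "multiply", 1.30)),
      start_date, ramp_weeks),
    intervention("psychiatrist_capacity",
      "Psychiatrist capacity growth increase",
      list(eff("capacity_growth.specialist", "add", 0.10)),
      start_date, ramp_weeks),
    intervention("allied_health_capacity",
      "Allied mental health capacity growth increase",
      list(eff("capacity_growth.specialist", "add", 0.06)),
      start_date, ramp_weeks),
    intervention("community_acute_care", "Community-based acute care services",
      list(eff("capacity_growth.inpatient", "add", 0.04),
           eff("attempt_rate_postdischarge", "multiply", 0.88,
               reach_param = "ed_presentation_rate", reach_ref = 0.008)),
      start_date, ramp_weeks),
    intervention("cmhc_capacity",
      "Community mental healthcare capacity growth increase",
      list(eff("capacity_growth.cmhc", "add", 0.05)),
      start_date, ramp_weeks),
    intervention("gp_capacity", "General practice capacity growth increase",
      list(eff("capacity_growth.gp", "add", 0.04)),
      start_date, ramp_weeks, reconstruction = TRUE),
    intervention("online_services", "Expanded online services uptake",
      list(eff("direct_online_fraction", "multiply", 1.30)),
      start_date, ramp_weeks, reconstruction = TRUE),
    intervention("ed_aftercare_outreach",
      "Emergency department aftercare outreach",
      list(eff("attempt_rate_postdischarge", "multiply", 0.90,
               reach_param = "ed_presentation_rate", reach_ref = 0.008)),
      start_date, ramp_weeks, reconstruction = TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "id"))
}

#' An unordered set of catalogue interventions
#'
#' @param ids character vector of intervention ids (possibly empty).
#' @param catalogue the catalogue the ids must come from.
#' @return Object of class `intervention_set` (a sorted character vector).
#' @export
intervention_set <- function(ids = character(),
                             catalogue = default_catalogue()) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate intervention ids", call. = FALSE)
  unknown <- setdiff(ids, names(catalogue))
  if (length(unknown)) {
    stop("unknown intervention id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(sort(ids), class = "intervention_set")
}

# Resolve an interventions argument (NULL / character / intervention_set /
# list of intervention objects) into a list of intervention objects.
resolve_interventions <- function(interventions, catalogue) {
  if (is.null(interventions) || length(interventions) == 0) return(list())
  if (inherits(interventions, "intervention")) return(list(interventions))
  if (is.character(interventions) || inherits(interventions, "intervention_set")) {
    ids <- intervention_set(as.character(interventions), catalogue)
    return(unname(catalogue[as.character(ids)]))
  }
  if (is.list(interventions) &&
      all(vapply(interventions, inherits, logical(1), "intervention"))) {
    return(interventions)
  }
  stop("`interventions` must be NULL, ids, an intervention_set, or a list of interventions",
       call. = FALSE)
}

#' Compile interventions into a numeric effects table
#'
#' Resolves reach scaling against the catchment, converts start dates to
#' model weeks on the grid, and returns the matrix form consumed by both
#' integration engines: columns `param` (index into the canonical flat
#' parameter vector), `mode` (1 multiply, 2 add, 3 replace), `magnitude`
#' (realised), `start_week`, `ramp_weeks`. Two members replace-targeting the
#' same path is a configuration conflict and errors.
#'
#' @param interventions as in [simulate_catchment()].
#' @param p the catchment the effects will act on (for reach scaling).
#' @param grid a [time_grid()].
#' @param catalogue the intervention catalogue.
#' @return A numeric matrix (possibly 0-row), or `NULL` when no
#'   interventions apply.
#' @export
prepare_effects <- function(interventions, p, grid,
                            catalogue = default_catalogue()) {
  members <- resolve_interventions(interventions, catalogue)
  if (!length(members)) return(NULL)
  paths <- param_names_flat()
  rows <- list()
  replace_seen <- character()
  for (iv in members) {
    start_week <- week_of_date(grid, iv$start_date)
    for (e in iv$effects) {
      mag <- e$magnitude
      if (!is.null(e$reach_param)) {
        if (e$mode != "multiply") {
          stop("reach scaling is defined for multiply effects only",
               call. = FALSE)
        }
        reach <- min(e$reach_cap, param_get(p, e$reach_param) / e$reach_ref)
        mag <- 1 - (1 - e$magnitude) * reach
        if (mag <= 0) mag <- 1e-6
      }
      if (e$mode == "replace") {
        if (e$path %in% replace_seen) {
          stop("two interventions replace-target the same parameter: ",
               e$path, call. = FALSE)
        }
        replace_seen <- c(replace_seen, e$path)
      }
      rows[[length(rows) + 1]] <- c(
        param = match(e$path, paths),
        mode = match(e$mode, c("multiply", "add", "replace")),
        magnitude = mag,
        start_week = start_week,
        ramp_weeks = iv$ramp_weeks
      )
    }
  }
  do.call(rbind, rows)
}

# Apply a compiled effects table to the base flat parameter vector at model
# week t. Multiplies compose commutatively, then adds, then replaces; each
# effect ramps linearly from its start over its ramp length.
effective_param_vector <- function(v0, effects, t) {
  if (is.null(effects) || nrow(effects) == 0) return(v0)
  v <- v0
  phi <- (t - effects[, 4]) / pmax(effects[, 5], .Machine$double.eps)
  phi[effects[, 5] == 0] <- as.numeric(t >= effects[effects[, 5] == 0, 4])
  phi <- pmin(pmax(phi, 0), 1)
  for (j in seq_len(nrow(effects))) {
    if (effects[j, 2] == 1 && phi[j] > 0) {
      i <- effects[j, 1]
      v[i] <- v[i] * (1 + (effects[j, 3] - 1) * phi[j])
    }
  }
  for (j in seq_len(nrow(effects))) {
    if (effects[j, 2] == 2 && phi[j] > 0) {
      i <- effects[j, 1]
      v[i] <- v[i] + effects[j, 3] * phi[j]
    }
  }
  for (j in seq_len(nrow(effects))) {
    if (effects[j, 2] == 3 && phi[j] > 0) {
      i <- effects[j, 1]
      v[i] <- v0[i] + (effects[j, 3] - v0[i]) * phi[j]
    }
  }
  v
}

#' Effective catchment parameters at a time point
#'
#' Applies an intervention set's direct effects to a parameter set at model
#' week `t_weeks`: before the start date parameters are unchanged; after
#' start + ramp all effects are fully composed; in between they ramp
#' linearly.
#'
#' @param p a [catchment_parameters()] object.
#' @param set interventions (ids, `intervention_set`, or list).
#' @param t_weeks model week on `grid`.
#' @param grid a [time_grid()].
#' @param catalogue the intervention catalogue.
#' @return A `catchment_parameters` object with effective values.
#' @export
apply_interventions <- function(p, set, t_weeks, grid,
                                catalogue = default_catalogue()) {
  effects <- prepare_effects(set, p, grid, catalogue)
  v0 <- param_vector(p)
  v <- effective_param_vector(v0, effects, t_weeks)
  changed <- which(v != v0)
  out <- p
  for (i in changed) out <- param_set(out, param_names_flat()[i], v[[i]])
  out
}
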