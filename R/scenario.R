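#' Forecast window for scenario comparisons
#'
#' The window over which cumulative suicides are compared between scenarios.
#' Both ends must fall on model-year boundaries of the grid; the default is
#' the 10-year window from 1 January 2021 to the start of 2031 on the
#' standard 2011-start grid.
#'
#' @param start,end calendar dates.
#' @return Object of class `forecast_window`.
#' @export
forecast_window <- function(start = "2021-01-01", end = "2031-01-01") {
  start <- as.Date(start); end <- as.Date(end)
  if (start >= end) stop("window start must precede its end", call. = FALSE)
  structure(list(start = start, end = end), class = "forecast_window")
}

window_years <- function(window, grid) {
  w0 <- week_of_date(grid, window$start)
  w1 <- week_of_date(grid, window$end)
  y0 <- w0 / 52
  y1 <- w1 / 52
  if (abs(y0 - round(y0)) > 1e-9 || abs(y1 - round(y1)) > 1e-9) {
    stop("forecast window must start and end on model-year boundaries",
         call. = FALSE)
  }
  y0 <- as.integer(round(y0)); y1 <- as.integer(round(y1))
  if (y0 < 0 || y1 > grid$horizon_years) {
    stop("forecast window lies outside the simulation grid", call. = FALSE)
  }
  list(from = y0, to = y1)
}

new_scenario_result <- function(catchment, ids, cumulative, baseline) {
  reduction <- baseline - cumulative
  structure(
    list(catchment = catchment,
         interventions = ids,
         cumulative_suicides = cumulative,
         baseline_suicides = baseline,
         reduction = reduction,
         pct_reduction = if (baseline > 0) 100 * reduction / baseline else 0),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> %s | {%s} | suicides %.1f (baseline %.1f), reduction %.1f (%.2f%%)\n",
    x$catchment,
    paste(x$interventions, collapse = ", "),
    x$cumulative_suicides, x$baseline_suicides, x$reduction, x$pct_reduction
  ))
  invisible(x)
}

#' @export
as.data.frame.scenario_result <- function(x, ...) {
  data.frame(catchment = x$catchment,
             set_ids = paste(x$interventions, collapse = "+"),
             k = length(x$interventions),
             cumulative_suicides = x$cumulative_suicides,
             baseline_suicides = x$baseline_suicides,
             reduction = x$reduction,
             pct_reduction = x$pct_reduction,
             stringsAsFactors = FALSE)
}

#' Snapshot a catchment at the forecast-window opening
#'
#' Runs the business-as-usual model from the grid start to the window start
#' and returns the state there. Interventions only act from the window start,
#' so the pre-window trajectory is shared by every scenario; snapshotting it
#' once makes the exhaustive combination search cheap without changing any
#' result (Euler integration restarted from a step boundary state is exact).
#'
#' @param p a [catchment_parameters()] object.
#' @param grid a [time_grid()].
#' @param window a [forecast_window()].
#' @param engine integration engine.
#' @return List with `state` (stock vector at window start), `from_year`,
#'   `to_year`.
#' @export
catchment_snapshot <- function(p, grid, window, engine = "cpp") {
  wy <- window_years(window, grid)
  if (wy$from == 0) {
    state <- initial_model_state(p)
  } else {
    pre <- simulate_catchment(p, grid, interventions = NULL, engine = engine)
    idx <- wy$from * 52L * grid$steps_per_week + 1L
    state <- pre$states[idx, ]
  }
  list(state = state, from_year = wy$from, to_year = wy$to)
}

run_window <- function(p, ids, grid, window, catalogue, snapshot, engine) {
  n_keep <- (snapshot$to_year - snapshot$from_year) * 52L *
    grid$steps_per_week + 1L
  traj <- simulate_catchment(
    p, grid, interventions = ids, catalogue = catalogue, engine = engine,
    from_year = snapshot$from_year, state0 = snapshot$state
  )
  unname(traj$states[n_keep, "CumSuicides"] - traj$states[1, "CumSuicides"])
}

#' Business-as-usual projection for one catchment
#'
#' The baseline scenario: no new interventions, existing services retained,
#' capacity growing at current rates. By definition its reduction is zero.
#'
#' @inheritParams catchment_snapshot
#' @param snapshot optional precomputed [catchment_snapshot()].
#' @return A `scenario_result` with an empty intervention set.
#' @export
run_baseline <- function(p, grid, window = forecast_window(),
                         engine = "cpp", snapshot = NULL) {
  if (is.null(snapshot)) snapshot <- catchment_snapshot(p, grid, window, engine)
  cum <- run_window(p, character(), grid, window, default_catalogue(),
                    snapshot, engine)
  new_scenario_result(p$name, character(), cum, cum)
}

#' Run one intervention scenario for one catchment
#'
#' Simulates the catchment with the given intervention set active from the
#' window start and compares cumulative suicides over the forecast window
#' with the baseline. Reductions may be negative: scenarios that increase
#' suicides (e.g. demand-generating campaigns in capacity-starved
#' catchments) are reported as such.
#'
#' @inheritParams run_baseline
#' @param set intervention ids (or an `intervention_set`).
#' @param catalogue the intervention catalogue.
#' @param baseline optional precomputed [run_baseline()] result.
#' @return A `scenario_result`.
#' @export
run_scenario <- function(p, set, grid, window = forecast_window(),
                         catalogue = default_catalogue(), engine = "cpp",
                         snapshot = NULL, baseline = NULL) {
  ids <- intervention_set(set, catalogue)
  if (is.null(snapshot)) snapshot <- catchment_snapshot(p, grid, window, engine)
  if (is.null(baseline)) {
    baseline <- run_baseline(p, grid, window, engine, snapshot)
  }
  cum <- run_window(p, ids, grid, window, catalogue, snapshot, engine)
  new_scenario_result(p$name, as.character(ids), cum,
                      baseline$cumulative_suicides)
}

#' Enumerate all k-subsets of the intervention catalogue
#'
#' Deterministic lexicographic order over the catalogue's own ordering; no
#' duplicates. `C(13, 4) = 715` and `C(13, 5) = 1287`.
#'
#' @param catalogue the catalogue (or a character vector of ids).
#' @param k subset size, `0 <= k <= length(catalogue)`.
#' @return List of character vectors of ids.
#' @export
enumerate_combinations <- function(catalogue, k) {
  ids <- if (is.character(catalogue)) catalogue else names(catalogue)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 0 ||
      k > length(ids)) {
    stop("`k` must be a whole number in [0, |catalogue|]", call. = FALSE)
  }
  if (k == 0) return(list(character()))
  combos <- utils::combn(ids, k, simplify = FALSE)
  combos
}

#' Sum per-catchment reductions into a state-level effect
#'
#' @param results list of `scenario_result`s, one per catchment, all for the
#'   same intervention set.
#' @return The exact sum of reductions (persons).
#' @export
state_level_effect <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "scenario_result")))
  sets <- lapply(results, function(r) sort(r$interventions))
  if (length(unique(vapply(sets, paste, character(1), collapse = "+"))) != 1) {
    stop("results carry different intervention sets", call. = FALSE)
  }
  sum(vapply(results, `[[`, numeric(1), "reduction"))
}

#' Exhaustive combination search over a set of catchments
#'
#' Runs every k-subset of the catalogue in every catchment (from shared
#' baseline snapshots) and collects the full reduction matrix. This is the
#' engine behind [optimal_state_combination()], [regional_planning_benefit()]
#' and [suboptimality_count()]; computing it once and passing it to all
#' three avoids re-simulation. Results are independent of catchment or set
#' evaluation order.
#'
#' @param catchments list of [catchment_parameters()] objects.
#' @param k subset size.
#' @param grid a [time_grid()].
#' @param window a [forecast_window()].
#' @param catalogue the intervention catalogue.
#' @param engine integration engine.
#' @return Object of class `combination_search`: list with `sets` (list of id
#'   vectors), `catchments` (names), `baseline` (named vector of baseline
#'   cumulative suicides), `reductions` (matrix, sets x catchments), `k`.
#' @export
combination_search <- function(catchments, k, grid,
                               window = forecast_window(),
                               catalogue = default_catalogue(),
                               engine = "cpp") {
  stopifnot(length(catchments) >= 1)
  sets <- enumerate_combinations(catalogue, k)
  nm <- vapply(catchments, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("catchment names must be unique", call. = FALSE)
  reductions <- matrix(NA_real_, nrow = length(sets), ncol = length(nm),
                       dimnames = list(NULL, nm))
  baseline <- stats::setNames(numeric(length(nm)), nm)
  for (j in seq_along(catchments)) {
    p <- catchments[[j]]
    snap <- catchment_snapshot(p, grid, window, engine)
    base <- run_window(p, character(), grid, window, catalogue, snap, engine)
    baseline[j] <- base
    for (i in seq_along(sets)) {
      cum <- run_window(p, sets[[i]], grid, window, catalogue, snap, engine)
      reductions[i, j] <- base - cum
    }
  }
  structure(list(sets = sets, catchments = nm, baseline = baseline,
                 reductions = reductions, k = k),
            class = "combination_search")
}

#' @export
print.combination_search <- function(x, ...) {
  cat(sprintf("<combination_search> %d sets of %d x %d catchment(s)\n",
              length(x$sets), x$k, length(x$catchments)))
  invisible(x)
}

# Reductions rounded for comparisons so float noise cannot reorder ties.
round_red <- function(x) round(x, 6)

#' Optimal state-level intervention combination
#'
#' Exhaustive search for the k-subset maximising the summed reduction in
#' suicides across all catchments when implemented in every catchment. Ties
#' (after rounding reductions to 1e-6 persons) are broken in favour of the
#' lexicographically earlier set.
#'
#' @inheritParams combination_search
#' @param search optional precomputed [combination_search()].
#' @return List with `set` (ids), `state_reduction`, `per_catchment` (named
#'   reductions vector), `baseline_total`, `pct_reduction`, `index`, and the
#'   `search` object used.
#' @export
optimal_state_combination <- function(catchments = NULL, k = NULL,
                                      grid = NULL,
                                      window = forecast_window(),
                                      catalogue = default_catalogue(),
                                      engine = "cpp", search = NULL) {
  if (is.null(search)) {
    search <- combination_search(catchments, k, grid, window, catalogue,
                                 engine)
  }
  totals <- round_red(rowSums(search$reductions))
  best <- which.max(totals)
  baseline_total <- sum(search$baseline)
  list(set = search$sets[[best]],
       state_reduction = sum(search$reductions[best, ]),
       per_catchment = search$reductions[best, ],
       baseline_total = baseline_total,
       pct_reduction = 100 * sum(search$reductions[best, ]) / baseline_total,
       index = best,
       search = search)
}

#' Benefit of regional over centralised planning for one catchment
#'
#' The extra suicides prevented when a catchment implements its own optimal
#' k-subset instead of the optimal state-level subset. Non-negative by
#' construction (the catchment optimum dominates any fixed set), and exactly
#' zero when the catchment optimum *is* the state optimum.
#'
#' @param state_opt result of [optimal_state_combination()].
#' @param catchment catchment name (a column of the search).
#' @return List with `catchment`, `optimal_set`, `catchment_reduction`,
#'   `state_set_reduction`, `benefit` (persons), `pct_of_baseline`.
#' @export
regional_planning_benefit <- function(state_opt, catchment) {
  search <- state_opt$search
  j <- match(catchment, search$catchments)
  if (is.na(j)) stop("unknown catchment: ", catchment, call. = FALSE)
  col <- round_red(search$reductions[, j])
  best_i <- which.max(col)
  benefit <- search$reductions[best_i, j] -
    search$reductions[state_opt$index, j]
  if (round_red(benefit) <= 0) {
    # ties resolve to the state set: no regional benefit
    best_i <- state_opt$index
    benefit <- 0
  }
  list(catchment = catchment,
       optimal_set = search$sets[[best_i]],
       catchment_reduction = search$reductions[best_i, j],
       state_set_reduction = search$reductions[state_opt$index, j],
       benefit = benefit,
       pct_of_baseline = 100 * benefit / search$baseline[[j]])
}

#' Count suboptimal intervention combinations in a catchment
#'
#' The number of enumerated k-subsets preventing *strictly* fewer suicides in
#' the catchment than the optimal state-level subset does there, plus that
#' count's share of the enumeration size.
#'
#' @inheritParams regional_planning_benefit
#' @return List with `count`, `n_sets`, `share_pct`.
#' @export
suboptimality_count <- function(state_opt, catchment) {
  search <- state_opt$search
  j <- match(catchment, search$catchments)
  if (is.na(j)) stop("unknown catchment: ", catchment, call. = FALSE)
  ref <- round_red(search$reductions[state_opt$index, j])
  col <- round_red(search$reductions[, j])
  count <- sum(col < ref)
  list(count = count, n_sets = length(col),
       share_pct = 100 * count / length(col))
}

#' Tidy scenario table from a combination search
#'
#' @param search a [combination_search()].
#' @return A `data.frame` with one row per (set, catchment):
#'   `catchment`, `k`, `set_ids`, `cumulative_suicides`, `reduction`,
#'   `pct_reduction`.
#' @export
scenario_table <- function(search) {
  stopifnot(inherits(search, "combination_search"))
  ids <- vapply(search$sets, paste, character(1), collapse = "+")
  out <- expand.grid(set_index = seq_along(search$sets),
                     catchment = search$catchments,
                     stringsAsFactors = FALSE)
  out$k <- search$k
  out$set_ids <- ids[out$set_index]
  red <- search$reductions[cbind(out$set_index,
                                 match(out$catchment, search$catchments))]
  base <- search$baseline[out$catchment]
  out$cumulative_suicides <- base - red
  out$reduction <- red
  out$pct_reduction <- 100 * red / base
  out$set_index <- NULL
  rownames(out) <- NULL
  out
}
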