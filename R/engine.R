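#' Generic fixed-step stock-and-flow engine
#'
#' A minimal explicit-Euler integrator over a fixed, named stock set, the
#' standard integration family for system dynamics models. The flow evaluator
#' is a function `flows(state, t)` returning a named vector of net rates (per
#' week) for every stock; stocks are updated as
#' `stock + dt * rate`, then clamped at zero (with a warning) if a step would
#' drive a stock negative.
#'
#' @param state named numeric vector of current stock values (all >= 0).
#' @param flows function `(state, t) -> named numeric` of net per-week rates;
#'   must return a rate for every stock and nothing else.
#' @param t_weeks current time in model weeks.
#' @param dt_weeks integration step in weeks.
#' @return The updated state (same names, same order).
#' @examples
#' euler_step(c(S = 100), function(s, t) c(S = -0.1 * s[["S"]]), 0, 1 / 8)
#' @export
euler_step <- function(state, flows, t_weeks, dt_weeks) {
  rates <- flows(state, t_weeks)
  rates <- check_rates(rates, state)
  out <- state + dt_weeks * rates
  neg <- out < 0
  if (any(neg)) {
    warning(sprintf(
      "stock(s) clamped at zero: %s", paste(names(state)[neg], collapse = ", ")
    ), call. = FALSE)
    out[neg] <- 0
  }
  out
}

check_rates <- function(rates, state) {
  if (is.null(names(rates)) || !setequal(names(rates), names(state))) {
    unknown <- setdiff(names(rates), names(state))
    if (length(unknown)) {
      stop("flow evaluator returned rate(s) for unknown stock(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    stop("flow evaluator must return one rate per stock", call. = FALSE)
  }
  rates <- rates[names(state)]
  if (any(!is.finite(rates))) {
    stop("non-finite flow rate for stock(s): ",
         paste(names(state)[!is.finite(rates)], collapse = ", "),
         call. = FALSE)
  }
  rates
}

#' Integrate a stock-and-flow model over a time grid
#'
#' Runs repeated [euler_step()] calls over the whole grid, recording the state
#' at every step boundary and, optionally, a set of auxiliary outputs
#' (prevalences, waiting times, instantaneous flow rates). The run is fully
#' deterministic: identical inputs give bit-identical trajectories.
#'
#' @param initial_state named numeric vector of starting stock values.
#' @param flows flow evaluator, as in [euler_step()].
#' @param grid a [time_grid()].
#' @param auxiliaries optional function `(state, t) -> named numeric` of
#'   auxiliary outputs, recorded at every step boundary.
#' @return An object of class `trajectory`: list with `grid`, `times` (weeks),
#'   `states` (matrix, `n_steps + 1` rows, one column per stock) and `aux`
#'   (matrix or `NULL`).
#' @export
integrate_model <- function(initial_state, flows, grid, auxiliaries = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  if (is.null(names(initial_state)) || any(!nzchar(names(initial_state)))) {
    stop("initial state must be a fully named numeric vector", call. = FALSE)
  }
  if (any(initial_state < 0)) stop("initial stocks must be >= 0", call. = FALSE)

  n <- grid$n_steps
  times <- grid_times(grid)
  states <- matrix(NA_real_, nrow = n + 1, ncol = length(initial_state),
                   dimnames = list(NULL, names(initial_state)))
  states[1, ] <- initial_state
  aux <- NULL
  if (!is.null(auxiliaries)) {
    a0 <- auxiliaries(initial_state, 0)
    aux <- matrix(NA_real_, nrow = n + 1, ncol = length(a0),
                  dimnames = list(NULL, names(a0)))
    aux[1, ] <- a0
  }
  state <- initial_state
  for (k in seq_len(n)) {
    state <- tryCatch(
      euler_step(state, flows, times[k], grid$dt_weeks),
      error = function(e) {
        stop(sprintf("integration failed at step %d (t = %.4f weeks): %s",
                     k, times[k], conditionMessage(e)), call. = FALSE)
      }
    )
    states[k + 1, ] <- state
    if (!is.null(aux)) aux[k + 1, ] <- auxiliaries(state, times[k + 1])
  }
  new_trajectory(grid, times, states, aux)
}

new_trajectory <- function(grid, times, states, aux = NULL) {
  structure(
    list(grid = grid, times = times, states = states, aux = aux),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d stocks x %d step boundaries (%d model years)\n",
    ncol(x$states), nrow(x$states), x$grid$horizon_years
  ))
  invisible(x)
}

#' Export a trajectory as a tidy long table
#'
#' One row per (step boundary, variable), covering stocks and auxiliaries,
#' with both model-week time and the corresponding calendar date.
#'
#' @param traj a `trajectory`.
#' @param thin keep every `thin`-th step boundary (default 1 = all).
#' @return A `data.frame` with columns `time_weeks`, `date`, `variable`,
#'   `value`.
#' @export
trajectory_table <- function(traj, thin = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- seq(1, length(traj$times), by = thin)
  vals <- traj$states[keep, , drop = FALSE]
  if (!is.null(traj$aux)) vals <- cbind(vals, traj$aux[keep, , drop = FALSE])
  tw <- traj$times[keep]
  data.frame(
    time_weeks = rep(tw, times = ncol(vals)),
    date = rep(traj$grid$start_date + round(tw * 7), times = ncol(vals)),
    variable = rep(colnames(vals), each = length(keep)),
    value = as.vector(vals),
    stringsAsFactors = FALSE
  )
}
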