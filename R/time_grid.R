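#' Simulation time grid
#'
#' Builds the fixed-step simulation calendar. Time is measured in weeks; one
#' model year is defined as 52 weeks, so a 20-year horizon spans 1040 weeks.
#' The default integration step is one-eighth of a week (0.875 days), the
#' standard choice for weekly-rate system dynamics models of this kind. The
#' small calendar drift this convention introduces (about 1.25 days per year
#' relative to the civil calendar) is accepted and documented.
#'
#' @param start_date start of the simulation, a `Date` (or string coercible to
#'   one). Default 2011-01-01.
#' @param horizon_years length of the run in model years (52-week years).
#' @param steps_per_week number of integration steps per week; `dt` is its
#'   reciprocal.
#'
#' @return An object of class `time_grid`: a list with fields `start_date`,
#'   `horizon_years`, `horizon_weeks`, `steps_per_week`, `dt_weeks`, `dt_days`
#'   and `n_steps`.
#' @examples
#' g <- time_grid("2011-01-01", 20, 8)
#' g$dt_days   # 0.875
#' g$n_steps   # 8320
#' @export
time_grid <- function(start_date = "2011-01-01", horizon_years = 20,
                      steps_per_week = 8) {
  start_date <- tryCatch(as.Date(start_date), error = function(e) NA)
  if (is.na(start_date)) stop("`start_date` is not a valid date", call. = FALSE)
  if (!is.numeric(horizon_years) || length(horizon_years) != 1 ||
      horizon_years < 1 || horizon_years != round(horizon_years)) {
    stop("`horizon_years` must be a positive whole number", call. = FALSE)
  }
  if (!is.numeric(steps_per_week) || length(steps_per_week) != 1 ||
      steps_per_week < 1 || steps_per_week != round(steps_per_week)) {
    stop("`steps_per_week` must be a positive whole number", call. = FALSE)
  }
  horizon_weeks <- 52L * as.integer(horizon_years)
  structure(
    list(
      start_date = start_date,
      horizon_years = as.integer(horizon_years),
      horizon_weeks = horizon_weeks,
      steps_per_week = as.integer(steps_per_week),
      dt_weeks = 1 / steps_per_week,
      dt_days = 7 / steps_per_week,
      n_steps = horizon_weeks * as.integer(steps_per_week)
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> start %s, %d model years (%d weeks), dt = 1/%d week (%.4g days), %d steps\n",
    format(x$start_date), x$horizon_years, x$horizon_weeks,
    x$steps_per_week, x$dt_days, x$n_steps
  ))
  invisible(x)
}

#' Simulation times of the step boundaries, in weeks since the start
#'
#' @param grid a [time_grid()].
#' @return Numeric vector of length `n_steps + 1`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  seq(0, by = grid$dt_weeks, length.out = grid$n_steps + 1)
}

#' Convert a calendar date to model weeks since the grid start
#'
#' Model years are 52 weeks; a calendar date is mapped through whole calendar
#' years plus a day fraction, so that anniversaries of the start date land on
#' exact multiples of 52 weeks (2021-01-01 on a 2011-01-01 grid is week 520).
#'
#' @param grid a [time_grid()].
#' @param date a `Date` (or string coercible to one).
#' @return Time in model weeks (not necessarily an integer).
#' @export
week_of_date <- function(grid, date) {
  stopifnot(inherits(grid, "time_grid"))
  date <- as.Date(date)
  y0 <- as.integer(format(grid$start_date, "%Y"))
  y1 <- as.integer(format(date, "%Y"))
  anniversary <- as.Date(sprintf(
    "%04d-%s", y1, format(grid$start_date, "%m-%d")
  ))
  52 * (y1 - y0) + as.numeric(date - anniversary) / 7
}

#' Index of the step boundary at (or nearest to) a model-week time
#'
#' @param grid a [time_grid()].
#' @param t_weeks time in model weeks.
#' @return Integer step index in `0:n_steps`.
#' @export
step_of_week <- function(grid, t_weeks) {
  k <- as.integer(round(t_weeks * grid$steps_per_week))
  if (any(k < 0 | k > grid$n_steps)) {
    stop("time outside the simulation grid", call. = FALSE)
  }
  k
}
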