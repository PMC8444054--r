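#' Mean absolute per cent error between observed and simulated yearly series
#'
#' The calibration objective: the mean over all observation points of
#' `100 * |observed - simulated| / observed`. Every observed `(metric, year)`
#' pair must have a simulated counterpart; all points are weighted equally.
#'
#' @param observed a `data.frame` with columns `metric`, `year`, `value`
#'   (values must be > 0), as read by [read_observed_series()].
#' @param simulated a yearly metrics table from [yearly_metrics()].
#' @return MAPE in per cent (scalar >= 0).
#' @examples
#' obs <- data.frame(metric = "suicides", year = 2011:2012, value = c(100, 200))
#' sim <- data.frame(year = 2011:2012, suicides = c(110, 190))
#' mape(obs, sim)  # mean(10%, 5%) = 7.5
#' @export
mape <- function(observed, simulated) {
  stopifnot(all(c("metric", "year", "value") %in% names(observed)))
  if (any(observed$value <= 0)) {
    stop("observed values must be positive (MAPE is undefined at zero)",
         call. = FALSE)
  }
  err <- numeric(nrow(observed))
  for (i in seq_len(nrow(observed))) {
    m <- observed$metric[i]
    if (!m %in% names(simulated)) {
      stop(sprintf("no simulated counterpart for metric '%s'", m),
           call. = FALSE)
    }
    row <- match(observed$year[i], simulated$year)
    if (is.na(row)) {
      stop(sprintf("no simulated counterpart for metric '%s' in year %d",
                   m, observed$year[i]), call. = FALSE)
    }
    err[i] <- abs(observed$value[i] - simulated[[m]][row]) / observed$value[i]
  }
  100 * mean(err)
}

#' Powell-type derivative-free minimisation with box bounds
#'
#' Direction-set minimisation: cycle through a set of search directions,
#' line-minimising along each with golden-section/Brent search
#' ([stats::optimize()]), then replace the direction of largest single
#' decrease with the cycle's net displacement direction and line-minimise
#' along it. Bounds are enforced by a smooth sinusoidal reparameterisation
#' (`x = lower + (upper - lower) * (sin(z) + 1) / 2`), so the directional
#' search is unconstrained and every visited point is feasible.
#'
#' @param fn objective, a function of the parameter vector.
#' @param x0 start values (inside the bounds).
#' @param lower,upper finite bounds, `lower < upper` elementwise.
#' @param reltol relative objective-change convergence tolerance.
#' @param maxit maximum direction-set cycles.
#' @return List with `par`, `value`, `iterations`, `evaluations`,
#'   `converged`, and `trace` (objective after each cycle).
#' @export
powell_minimize <- function(fn, x0, lower, upper, reltol = 1e-4,
                            maxit = 200) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n,
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  if (any(x0 < lower | x0 > upper)) {
    stop("start values must lie within the bounds", call. = FALSE)
  }
  to_x <- function(z) lower + (upper - lower) * (sin(z) + 1) / 2
  # initial z in the principal branch
  frac <- pmin(pmax((x0 - lower) / (upper - lower), 1e-9), 1 - 1e-9)
  z <- asin(2 * frac - 1)

  n_eval <- 0L
  fz <- function(zv) {
    n_eval <<- n_eval + 1L
    fn(to_x(zv))
  }
  if (n == 0) {
    return(list(par = x0, value = fn(x0), iterations = 0L, evaluations = 1L,
                converged = TRUE, trace = numeric()))
  }

  dirs <- diag(n)
  f_cur <- fz(z)
  trace <- numeric()
  converged <- FALSE
  it <- 0L
  line_min <- function(z, d, f_at_z) {
    g <- function(alpha) fz(z + alpha * d)
    opt <- stats::optimize(g, interval = c(-pi, pi))
    # fall back on a finer bracketed pass around the coarse optimum
    opt2 <- stats::optimize(g, interval = opt$minimum + c(-0.3, 0.3))
    if (opt2$objective < opt$objective) opt <- opt2
    if (opt$objective < f_at_z) {
      list(z = z + opt$minimum * d, f = opt$objective,
           gain = f_at_z - opt$objective)
    } else {
      list(z = z, f = f_at_z, gain = 0)
    }
  }
  while (it < maxit) {
    it <- it + 1L
    z_start <- z
    f_start <- f_cur
    biggest <- 0
    biggest_i <- 1L
    for (i in seq_len(n)) {
      res <- line_min(z, dirs[, i], f_cur)
      if (res$gain > biggest) { biggest <- res$gain; biggest_i <- i }
      z <- res$z; f_cur <- res$f
    }
    d_net <- z - z_start
    if (sqrt(sum(d_net^2)) > 1e-12) {
      res <- line_min(z, d_net, f_cur)
      if (res$gain > 0) {
        z <- res$z; f_cur <- res$f
        dirs[, biggest_i] <- d_net / sqrt(sum(d_net^2))
      }
    }
    trace <- c(trace, f_cur)
    if (2 * abs(f_start - f_cur) <=
        reltol * (abs(f_start) + abs(f_cur) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(par = to_x(z), value = f_cur, iterations = it, evaluations = n_eval,
       converged = converged, trace = trace)
}

#' Define a calibration problem
#'
#' @param fixed a [catchment_parameters()] object providing every parameter
#'   not being fitted.
#' @param free a `data.frame` with columns `path` (dotted parameter path),
#'   `lower`, `upper`, `init`; bounds must be finite with `lower < upper` and
#'   `init` inside them.
#' @param targets observed series table (columns `metric`, `year`, `value`).
#' @return Object of class `calibration_problem`.
#' @export
calibration_problem <- function(fixed, free, targets) {
  stopifnot(inherits(fixed, "catchment_parameters"))
  if (nrow(free) > 0) {
    stopifnot(all(c("path", "lower", "upper", "init") %in% names(free)))
    for (i in seq_len(nrow(free))) {
      param_get(fixed, free$path[i])  # errors on unknown path
      if (!is.finite(free$lower[i]) || !is.finite(free$upper[i]) ||
          free$lower[i] >= free$upper[i]) {
        stop("bounds must be finite with lower < upper for ", free$path[i],
             call. = FALSE)
      }
      if (free$init[i] < free$lower[i] || free$init[i] > free$upper[i]) {
        stop("initial value outside bounds for ", free$path[i], call. = FALSE)
      }
    }
  }
  stopifnot(all(c("metric", "year", "value") %in% names(targets)))
  structure(list(fixed = fixed, free = free, targets = targets),
            class = "calibration_problem")
}

#' Calibrate free parameters against observed yearly series
#'
#' Minimises [mape()] between the observed series and the model's yearly
#' outputs over the free parameters, using the Powell-type direction-set
#' search in [powell_minimize()]. Deterministic given the initial values. If
#' the iteration budget is exhausted before the relative-change tolerance is
#' met, the best parameters found so far are returned with
#' `converged = FALSE` (no error).
#'
#' @param problem a [calibration_problem()].
#' @param grid a [time_grid()] covering all target years.
#' @param engine integration engine passed to [simulate_catchment()].
#' @param reltol,maxit convergence controls for [powell_minimize()].
#' @return List with `parameters` (a full `catchment_parameters` object at
#'   the optimum), `estimates` (named vector of fitted values), `mape`,
#'   `initial_mape`, `iterations`, `evaluations`, `converged`, `trace`.
#' @export
calibrate <- function(problem, grid, engine = "cpp", reltol = 1e-4,
                      maxit = 200) {
  stopifnot(inherits(problem, "calibration_problem"))
  years <- sort(unique(problem$targets$year))
  y0 <- as.integer(format(grid$start_date, "%Y"))
  if (min(years) < y0 || max(years) > y0 + grid$horizon_years - 1) {
    stop("grid does not cover the observed years", call. = FALSE)
  }
  free <- problem$free
  objective <- function(x) {
    p <- problem$fixed
    for (i in seq_along(x)) p <- param_set(p, free$path[i], x[[i]])
    traj <- simulate_catchment(p, grid, engine = engine)
    mape(problem$targets, yearly_metrics(traj))
  }
  if (nrow(free) == 0) {
    m <- objective(numeric())
    return(list(parameters = problem$fixed, estimates = numeric(),
                mape = m, initial_mape = m, iterations = 0L,
                evaluations = 1L, converged = TRUE, trace = numeric()))
  }
  initial_mape <- objective(free$init)
  res <- powell_minimize(objective, free$init, free$lower, free$upper,
                         reltol = reltol, maxit = maxit)
  # monotone improvement guarantee: never report worse than the start point
  if (res$value > initial_mape) {
    res$par <- free$init
    res$value <- initial_mape
  }
  p_fit <- problem$fixed
  for (i in seq_len(nrow(free))) {
    p_fit <- param_set(p_fit, free$path[i], res$par[[i]])
  }
  list(parameters = p_fit,
       estimates = stats::setNames(res$par, free$path),
       mape = res$value, initial_mape = initial_mape,
       iterations = res$iterations, evaluations = res$evaluations,
       converged = res$converged, trace = res$trace)
}
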