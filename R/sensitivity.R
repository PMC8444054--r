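#' Latin hypercube design over intervention effect magnitudes
#'
#' Builds the uncertainty-propagation design: for each listed parameter a
#' uniform range (default +/-20% of its default value) is divided into
#' `n` equal-probability strata and exactly one draw falls in each stratum
#' (Latin hypercube sampling). Deterministic given `seed`; the global RNG
#' state is restored afterwards.
#'
#' @param defaults named numeric vector of parameter default values (the
#'   design is centred on these).
#' @param n number of draws (default 100).
#' @param frac half-width of the uniform range as a fraction of the default
#'   (default 0.2).
#' @param seed integer seed (required; logged in the design).
#' @param lower,upper optional explicit per-parameter bounds overriding
#'   `frac`.
#' @return Object of class `lhs_design`: list with `samples` (n x p matrix),
#'   `lower`, `upper`, `defaults`, `seed`.
#' @export
lhs_design <- function(defaults, n = 100, frac = 0.2, seed,
                       lower = NULL, upper = NULL) {
  stopifnot(is.numeric(defaults), length(defaults) >= 1,
            !is.null(names(defaults)), n >= 2)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(lower)) lower <- defaults * (1 - frac)
  if (is.null(upper)) upper <- defaults * (1 + frac)
  if (any(lower >= upper)) {
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  }
  u <- with_seed(seed, lhs::randomLHS(n, length(defaults)))
  samples <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(samples) <- names(defaults)
  structure(list(samples = samples, lower = lower, upper = upper,
                 defaults = defaults, seed = seed),
            class = "lhs_design")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Design over the direct-effect magnitudes of an intervention set
#'
#' Collects the effect magnitudes of the member interventions (named
#' `"<intervention id>:<parameter path>"`) as the sampled parameters — the
#' quantities whose uncertainty the sensitivity analysis propagates — and
#' builds an [lhs_design()] over them.
#'
#' @param set intervention ids.
#' @param catalogue the catalogue.
#' @inheritParams lhs_design
#' @return An `lhs_design`.
#' @export
sensitivity_design <- function(set, catalogue = default_catalogue(),
                               n = 100, frac = 0.2, seed) {
  members <- resolve_interventions(set, catalogue)
  if (!length(members)) stop("intervention set is empty", call. = FALSE)
  vals <- numeric(); nms <- character()
  for (iv in members) {
    for (e in iv$effects) {
      nms <- c(nms, paste0(iv$id, ":", e$path))
      vals <- c(vals, e$magnitude)
    }
  }
  lhs_design(stats::setNames(vals, nms), n = n, frac = frac, seed = seed)
}

# Rebuild a catalogue with the member interventions' magnitudes replaced by
# one design row.
perturb_catalogue <- function(catalogue, row) {
  for (nm in names(row)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    id <- parts[1]; path <- parts[2]
    iv <- catalogue[[id]]
    if (is.null(iv)) stop("design names unknown intervention: ", id,
                          call. = FALSE)
    hit <- FALSE
    for (i in seq_along(iv$effects)) {
      if (iv$effects[[i]]$path == path) {
        iv$effects[[i]]$magnitude <- row[[nm]]
        hit <- TRUE
      }
    }
    if (!hit) stop("design names unknown effect path: ", nm, call. = FALSE)
    catalogue[[id]] <- iv
  }
  catalogue
}

#' Propagate intervention-effect uncertainty through a scenario
#'
#' Re-runs the intervention scenario once per design draw with the sampled
#' effect magnitudes and returns the paired reductions against the baseline.
#' The sampled parameters act only from the intervention start date, so the
#' baseline is unaffected by them and is computed once. A draw whose
#' integration fails is recorded, excluded with a warning, and counted.
#'
#' @param p a [catchment_parameters()] object.
#' @param set intervention ids.
#' @param design an [lhs_design()] from [sensitivity_design()].
#' @param grid a [time_grid()].
#' @param window a [forecast_window()].
#' @param catalogue the catalogue.
#' @param engine integration engine.
#' @return Object of class `sensitivity_result`: list with `reductions`,
#'   `pct_reductions` (one per successful draw), `baseline_suicides`,
#'   `failed` (indices of failed draws), `design`.
#' @export
run_sensitivity <- function(p, set, design, grid,
                            window = forecast_window(),
                            catalogue = default_catalogue(),
                            engine = "cpp") {
  stopifnot(inherits(design, "lhs_design"))
  ids <- intervention_set(set, catalogue)
  snap <- catchment_snapshot(p, grid, window, engine)
  base <- run_window(p, character(), grid, window, catalogue, snap, engine)
  n <- nrow(design$samples)
  reductions <- rep(NA_real_, n)
  failed <- integer()
  for (d in seq_len(n)) {
    cat_d <- perturb_catalogue(catalogue, design$samples[d, ])
    cum <- tryCatch(
      run_window(p, ids, grid, window, cat_d, snap, engine),
      error = function(e) NA_real_
    )
    if (is.na(cum)) failed <- c(failed, d) else reductions[d] <- base - cum
  }
  if (length(failed)) {
    warning(sprintf("%d of %d draws failed integration and were excluded",
                    length(failed), n), call. = FALSE)
  }
  ok <- !is.na(reductions)
  structure(list(reductions = reductions[ok],
                 pct_reductions = 100 * reductions[ok] / base,
                 baseline_suicides = base,
                 failed = failed,
                 design = design),
            class = "sensitivity_result")
}

#' Percentile-interval summary of a sensitivity distribution
#'
#' Mean, 50% interval (25th--75th percentiles) and 95% interval
#' (2.5th--97.5th percentiles), using linear interpolation between order
#' statistics ([stats::quantile()] type 7). These intervals quantify the
#' consequence of uncertainty in the assumed intervention effects; they are
#' not confidence intervals and should not be read as such.
#'
#' @param samples numeric vector (length >= 2), e.g.
#'   `sensitivity_result$reductions`.
#' @return List with `mean`, `interval50` (length-2), `interval95`
#'   (length-2), `n`.
#' @export
summarize_intervals <- function(samples) {
  if (inherits(samples, "sensitivity_result")) samples <- samples$reductions
  if (length(samples) < 2) {
    stop("at least two samples are required", call. = FALSE)
  }
  q <- stats::quantile(samples, c(0.025, 0.25, 0.75, 0.975), names = FALSE,
                       type = 7)
  list(mean = mean(samples),
       interval50 = c(q[2], q[3]),
       interval95 = c(q[1], q[4]),
       n = length(samples))
}
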