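#' Read an observed yearly series file
#'
#' CSV with columns `metric`, `year`, `value` — the tabular interchange
#' format for calibration targets.
#'
#' @param path file path.
#' @return A validated `data.frame`.
#' @export
read_observed_series <- function(path) {
  if (!file.exists(path)) stop("observed series file not found: ", path,
                               call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metric", "year", "value")
  if (!all(need %in% names(obs))) {
    stop("observed series must have columns metric, year, value",
         call. = FALSE)
  }
  if (any(!is.finite(obs$value)) || any(obs$value <= 0)) {
    stop("observed values must be positive and finite", call. = FALSE)
  }
  for (m in unique(obs$metric)) {
    y <- obs$year[obs$metric == m]
    if (any(diff(sort(y)) == 0)) {
      stop("duplicate years for metric ", m, call. = FALSE)
    }
  }
  obs
}

#' Write an observed yearly series file
#'
#' @param obs a `data.frame` with columns `metric`, `year`, `value`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_observed_series <- function(obs, path) {
  stopifnot(all(c("metric", "year", "value") %in% names(obs)))
  utils::write.csv(obs[, c("metric", "year", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the settings echo, the
#' seeds, the package version and a timestamp, as YAML.
#'
#' @param path file path.
#' @param ... named settings to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  obj <- list(
    package = "phnsim",
    version = as.character(utils::packageVersion("phnsim")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    settings = list(...)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}
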