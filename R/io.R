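#' Read a program configuration file
#'
#' YAML (or JSON, which YAML parses) with keys:
#' ```
#' stages:          # ordered list; name, nominal_duration, pandemic_alos
#'   - {name: R1, nominal_duration: 1.0, pandemic_alos: 1.22}
#' initial_stocks: [12, 10, 10, 18, 12]
#' intake_rate: 12
#' scenario:        # optional
#'   onset: 0
#'   duration_T: 1
#'   baseline_impact: 1
#' simulation:      # optional
#'   horizon: 10
#'   dt: 0.25
#'   flow: conveyor
#' ```
#' Missing optional keys fall back to package defaults; missing
#' required keys raise a config error naming the key.
#'
#' @param path Path to the config file.
#' @return List with `config` (a [program_config()]), `scenario` (a
#'   [pandemic_scenario()]) and `simulation` (list `horizon`, `dt`,
#'   `flow`).
#' @export
read_program_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config(sprintf(
                    "cannot parse config '%s': %s", path, conditionMessage(e))))
  for (key in c("stages", "initial_stocks"))
    if (is.null(raw[[key]]))
      stop_config(sprintf("config '%s' is missing required key '%s'", path, key))
  stages <- lapply(raw$stages, function(s) {
    if (is.null(s$name)) stop_config("every stage needs a 'name' key")
    stage_spec(s$name,
               nominal_duration = s$nominal_duration %||% 1,
               pandemic_alos = s$pandemic_alos %||% s$nominal_duration %||% 1)
  })
  config <- program_config(stages,
                           initial_stocks = as.numeric(raw$initial_stocks),
                           intake_rate = raw$intake_rate %||%
                             as.numeric(raw$initial_stocks)[1L])
  sc <- raw$scenario %||% list()
  scenario <- pandemic_scenario(duration_T = sc$duration_T %||% 0,
                                onset = sc$onset %||% 0,
                                baseline_impact = sc$baseline_impact %||% 1)
  sim <- raw$simulation %||% list()
  simulation <- list(horizon = sim$horizon %||% 10,
                     dt = sim$dt %||% 0.25,
                     flow = sim$flow %||% "conveyor")
  if (!simulation$flow %in% c("conveyor", "first_order"))
    stop_config("simulation 'flow' must be 'conveyor' or 'first_order'")
  list(config = config, scenario = scenario, simulation = simulation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' Columns: `time` (4 decimal places), one stock column per stage,
#' `graduates_cumulative`, and `graduates_annual` (the year's graduate
#' count on whole-year rows, blank elsewhere).
#'
#' @param traj A trajectory from [simulate_program()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "residency_trajectory"))
  out <- as.data.frame(traj)
  annual <- rep("", nrow(out))
  rows <- .year_rows(traj)
  if (length(rows) >= 2L)
    annual[rows[-1L]] <- format(annual_graduates(traj), trim = TRUE)
  out$graduates_annual <- annual
  out$time <- sprintf("%.4f", out$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scenario-grid report to CSV
#'
#' One row per circuit-breaker duration, as produced by
#' [grid_report()]; unrecovered scenarios are written as `"NR"` in the
#' `time_to_bau` column.
#'
#' @param report A [grid_report()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(report, path) {
  out <- report
  out$time_to_bau <- ifelse(is.na(report$time_to_bau), "NR",
                            as.character(report$time_to_bau))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a calibration report to CSV
#'
#' @param report A [calibration_report()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
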