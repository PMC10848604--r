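#' Run a grid of circuit-breaker scenarios
#'
#' Simulates one trajectory per circuit-breaker duration `T`, always
#' including the T = 0 business-as-usual reference. Duplicated
#' durations are dropped with a warning; a missing 0 is inserted with a
#' message. If `auto_extend` is set and any scenario has not rejoined
#' the baseline by the horizon, the horizon is extended in 5-year
#' increments (up to `max_horizon`) so every recovery time is resolved.
#'
#' @param config A [program_config()].
#' @param durations Circuit-breaker durations in years (e.g. `0:5`).
#' @param horizon Simulation length in years.
#' @param dt Time step in years.
#' @param flow Flow law passed to [simulate_program()].
#' @param onset,baseline_impact Shared scenario parameters.
#' @param rel_tol Relative tolerance used by the recovery check when
#'   auto-extending (see [time_to_bau()]).
#' @param auto_extend Extend the horizon until all scenarios recover?
#' @param max_horizon Cap on automatic extension.
#' @return A `scenario_grid`: list with the shared `config`,
#'   `durations`, `horizon`, `dt`, `flow` and a named list
#'   `trajectories` (one per T).
#' @examples
#' grid <- run_scenario_grid(residency_example_config(), durations = 0:5)
#' grid_report(grid)
#' @export
run_scenario_grid <- function(config, durations = 0:5, horizon = 10,
                              dt = 0.25, flow = c("conveyor", "first_order"),
                              onset = 0, baseline_impact = 1,
                              rel_tol = 0.02, auto_extend = TRUE,
                              max_horizon = 40) {
  flow <- match.arg(flow)
  if (!is.numeric(durations) || length(durations) == 0L || any(durations < 0))
    stop_config("'durations' must be a non-empty vector of nonnegative years")
  if (anyDuplicated(durations)) {
    warning("duplicate durations dropped: ",
            paste(unique(durations[duplicated(durations)]), collapse = ", "))
    durations <- unique(durations)
  }
  if (!any(durations == 0)) {
    message("inserting T = 0 (business-as-usual reference) into the grid")
    durations <- c(0, durations)
  }
  durations <- sort(durations)

  build <- function(h) {
    trajs <- lapply(durations, function(T) {
      tryCatch(
        simulate_program(config, pandemic_scenario(T, onset, baseline_impact),
                         horizon = h, dt = dt, flow = flow),
        error = function(e) stop_model(sprintf("scenario T = %.3g failed: %s",
                                               T, conditionMessage(e))))
    })
    names(trajs) <- paste0("T=", durations)
    trajs
  }
  trajs <- build(horizon)
  if (auto_extend) {
    repeat {
      bau <- trajs[[which(durations == 0)]]
      ttb <- vapply(trajs, function(tr) time_to_bau(tr, bau, rel_tol), numeric(1))
      if (!anyNA(ttb) || horizon >= max_horizon) break
      horizon <- min(horizon + 5, max_horizon)
      message(sprintf("scenario(s) not recovered; extending horizon to %g years", horizon))
      trajs <- build(horizon)
    }
  }
  structure(list(config = config, durations = durations, horizon = horizon,
                 dt = dt, flow = flow, onset = onset,
                 baseline_impact = baseline_impact, rel_tol = rel_tol,
                 trajectories = trajs),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("<scenario_grid> %d scenarios (T = %s), horizon %g yr, %s flow\n",
              length(x$durations), paste(x$durations, collapse = ", "),
              x$horizon, x$flow))
  invisible(x)
}

#' Cumulative graduates over a window
#'
#' Total residents graduating during the first `window_years` of a
#' trajectory: cumulative graduates at the window end minus at time 0.
#'
#' @param traj A trajectory from [simulate_program()].
#' @param window_years Window length in years (0 to the horizon, must
#'   lie on the trajectory's time grid).
#' @return Number of graduates (nonnegative real).
#' @examples
#' traj <- simulate_program(residency_example_config(), horizon = 10)
#' cumulative_graduates(traj, 5)
#' @export
cumulative_graduates <- function(traj, window_years) {
  stopifnot(inherits(traj, "residency_trajectory"))
  if (!is_number(window_years) || window_years < 0)
    stop_config("'window_years' must be a single nonnegative number")
  horizon <- traj$time[nrow(traj)]
  if (window_years > horizon + 1e-9)
    stop_config(sprintf("window (%g yr) exceeds trajectory horizon (%g yr)",
                        window_years, horizon))
  idx <- which(abs(traj$time - window_years) < 1e-9)
  if (length(idx) != 1L)
    stop_config("'window_years' must lie on the trajectory time grid")
  traj$graduates_cumulative[idx] - traj$graduates_cumulative[1L]
}

#' Time to return to business as usual
#'
#' The number of whole years until a scenario's annual graduate output
#' rejoins the T = 0 baseline and stays there: the smallest year `y`
#' such that for every later year the scenario's annual graduates are
#' within `rel_tol` of the baseline's. A sustained criterion is used
#' rather than first crossing so that transient touches during the
#' recovery overshoot do not count as recovery.
#'
#' @param scenario_traj,bau_traj Trajectories from [simulate_program()]
#'   sharing config, horizon, dt and flow law; `bau_traj` must be the
#'   T = 0 run.
#' @param rel_tol Relative tolerance on annual graduates (default 0.02).
#'   For a year in which the baseline graduates nobody, the tolerance
#'   falls back to `rel_tol` times the baseline's mean annual output.
#' @return Recovery time in whole years (0 for identical trajectories),
#'   or `NA` if the scenario has not recovered within the horizon.
#' @examples
#' cfg <- residency_example_config()
#' bau <- simulate_program(cfg, pandemic_scenario(0), horizon = 12)
#' cb1 <- simulate_program(cfg, pandemic_scenario(1), horizon = 12)
#' time_to_bau(cb1, bau) # 6
#' @export
time_to_bau <- function(scenario_traj, bau_traj, rel_tol = 0.02) {
  stopifnot(inherits(scenario_traj, "residency_trajectory"),
            inherits(bau_traj, "residency_trajectory"))
  if (!is_number(rel_tol) || rel_tol <= 0)
    stop_config("'rel_tol' must be a single positive number")
  if (nrow(scenario_traj) != nrow(bau_traj) ||
      !isTRUE(all.equal(attr(scenario_traj, "dt"), attr(bau_traj, "dt"))) ||
      attr(scenario_traj, "flow") != attr(bau_traj, "flow") ||
      !identical(attr(scenario_traj, "config"), attr(bau_traj, "config")))
    stop_config("trajectories must share config, horizon, dt and flow law")
  a_s <- annual_graduates(scenario_traj)
  a_b <- annual_graduates(bau_traj)
  tol <- rel_tol * ifelse(a_b > 0, a_b, mean(a_b))
  ok <- abs(a_s - a_b) <= tol
  # recovered from year y if all years > y are within tolerance
  last_bad <- if (all(ok)) 0L else max(which(!ok))
  if (last_bad == length(ok) && !ok[length(ok)]) return(NA_integer_)
  as.integer(last_bad)
}

#' Summarise a scenario grid
#'
#' One row per circuit-breaker duration: cumulative graduates over the
#' reporting window, recovery time, and the per-year annual graduate
#' counts.
#'
#' @param grid A [run_scenario_grid()] result.
#' @param window_years Window for the cumulative-graduates column
#'   (default 5 years).
#' @param rel_tol Tolerance for [time_to_bau()]; defaults to the grid's.
#' @return Data frame with columns `duration_T`,
#'   `cumulative_graduates_<w>yr`, `time_to_bau` (NA = not recovered)
#'   and `year_1` ... `year_N`.
#' @export
grid_report <- function(grid, window_years = 5, rel_tol = grid$rel_tol) {
  stopifnot(inherits(grid, "scenario_grid"))
  bau <- grid$trajectories[[which(grid$durations == 0)]]
  rows <- lapply(seq_along(grid$durations), function(k) {
    tr <- grid$trajectories[[k]]
    ann <- annual_graduates(tr)
    out <- data.frame(duration_T = grid$durations[k],
                      cumulative = cumulative_graduates(tr, window_years),
                      time_to_bau = time_to_bau(tr, bau, rel_tol))
    out[names(ann)] <- as.list(ann)
    out
  })
  report <- do.call(rbind, rows)
  names(report)[2L] <- sprintf("cumulative_graduates_%gyr", window_years)
  report
}

#' Plot annual graduates for every scenario in a grid
#'
#' Annual graduate output versus year, one line per circuit-breaker
#' duration, with the T = 0 baseline emphasised. Requires ggplot2.
#'
#' @param grid A [run_scenario_grid()] result.
#' @return A ggplot object.
#' @export
plot_scenario_grid <- function(grid) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scenario_grid() requires the ggplot2 package")
  dat <- do.call(rbind, lapply(seq_along(grid$durations), function(k) {
    ann <- annual_graduates(grid$trajectories[[k]])
    data.frame(T = grid$durations[k], year = seq_along(ann), graduates = unname(ann))
  }))
  dat$T <- factor(dat$T)
  ggplot2::ggplot(dat, ggplot2::aes(x = year, y = graduates, colour = T,
                                    linewidth = T == "0")) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1.2, `FALSE` = 0.5),
                                    guide = "none") +
    ggplot2::labs(x = "Year", y = "Annual graduates",
                  colour = "Circuit breaker T (yr)",
                  title = "Annual specialist output by circuit-breaker duration") +
    ggplot2::theme_minimal()
}
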