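#' Effective average length of stay at a point in time
#'
#' Returns the mean time-in-stage that governs progression at time
#' `time`: the stage's nominal duration outside the circuit-breaker
#' window, and
#' `nominal + baseline_impact * (pandemic_alos - nominal)` while the
#' impact is active (`onset <= time < onset + duration_T`).
#'
#' @param stage A [stage_spec()].
#' @param scenario A [pandemic_scenario()].
#' @param time Time in years from simulation start (>= 0).
#' @return Effective ALOS in years.
#' @examples
#' sr1 <- stage_spec("SR1", pandemic_alos = 1.32)
#' effective_alos(sr1, pandemic_scenario(duration_T = 1), time = 0.5) # 1.32
#' effective_alos(sr1, pandemic_scenario(duration_T = 0), time = 0.5) # 1.00
#' @export
effective_alos <- function(stage, scenario, time) {
  stopifnot(inherits(stage, "stage_spec"), inherits(scenario, "pandemic_scenario"))
  if (!is_number(time) || time < 0)
    stop_config("'time' must be a single nonnegative number")
  .eff_alos(stage$nominal_duration, stage$pandemic_alos, scenario, time)
}

# vectorised over stages; scalar time
.eff_alos <- function(nominal, palos, scenario, time) {
  active <- scenario$duration_T > 0 &&
    time >= scenario$onset && time < scenario$onset + scenario$duration_T
  if (active) nominal + scenario$baseline_impact * (palos - nominal) else nominal
}

#' Stage outflow rate
#'
#' First-order outflow of a stock with mean residence time `alos`:
#' the rate at which residents leave a stage is `stock / alos`
#' (residents per year), so the mean time spent in the stage equals
#' the ALOS.
#'
#' @param stock Residents currently in the stage (>= 0).
#' @param alos Mean residence time in years (> 0).
#' @return Outflow in residents per year.
#' @examples
#' transfer_rate(18, 1.32) # 13.6364
#' @export
transfer_rate <- function(stock, alos) {
  if (!is.numeric(stock) || any(stock < 0))
    stop_config("'stock' must be nonnegative")
  if (!is.numeric(alos) || any(alos <= 0))
    stop_config("'alos' must be positive: invalid stage specification")
  stock / alos
}

#' One forward-Euler step of the first-order stock-and-flow engine
#'
#' Advances the pipeline state by `dt` years. The first stage receives
#' the intake rate; every later stage receives the outflow of its
#' predecessor; each stage drains at [transfer_rate()] evaluated at the
#' stage's [effective_alos()]; the last stage's outflow accrues to
#' cumulative graduates. Stocks are clipped at zero (unreachable for
#' `dt <= min(alos)`).
#'
#' @param state List with `time` (years), `stocks` (numeric, one per
#'   stage) and `graduates_cumulative`.
#' @param config A [program_config()].
#' @param scenario A [pandemic_scenario()].
#' @param dt Step size in years (> 0).
#' @return The updated state list.
#' @export
step_state <- function(state, config, scenario, dt) {
  if (!is_number(dt) || dt <= 0) stop_config("'dt' must be a single positive number")
  stopifnot(length(state$stocks) == n_stages(config))
  alos <- .eff_alos(config$stages$nominal_duration, config$stages$pandemic_alos,
                    scenario, state$time)
  out <- transfer_rate(state$stocks, alos)
  inflow <- c(config$intake_rate, out[-length(out)])
  list(time = state$time + dt,
       stocks = pmax(0, state$stocks + dt * (inflow - out)),
       graduates_cumulative = state$graduates_cumulative + dt * out[length(out)])
}

#' Simulate a residency pipeline under a pandemic scenario
#'
#' Runs the stock-and-flow model from the program's initial stocks over
#' `[0, horizon]` and returns the trajectory of per-stage stocks and
#' cumulative graduates on a uniform time grid. Two flow laws are
#' available:
#'
#' * `"conveyor"` (default): fixed-duration progression. Residents move
#'   as annual cohorts; a cohort entering a stage while the circuit
#'   breaker is active stays exactly the stage's effective ALOS, and
#'   exactly the nominal duration otherwise. Intake enters as discrete
#'   batches of `intake_rate` at whole years.
#' * `"first_order"`: aging-chain dynamics. Each stage drains
#'   continuously at `stock / effective_alos`, integrated by forward
#'   Euler with step `dt`; intake is a continuous inflow.
#'
#' Both laws conserve residents (intake in = stocks + graduates) and
#' revert to business-as-usual dynamics when the circuit breaker ends;
#' they differ in how sharply delayed cohorts flush out of the system.
#'
#' @param config A [program_config()].
#' @param scenario A [pandemic_scenario()]; default is business as usual.
#' @param horizon Simulation length in years (> 0).
#' @param dt Reporting (and, for `"first_order"`, integration) step in
#'   years; must divide 1 year exactly so annual aggregates are defined.
#' @param flow Flow law, `"conveyor"` or `"first_order"`.
#' @return A `residency_trajectory`: a data frame with columns `time`,
#'   one stock column per stage, and `graduates_cumulative`, carrying
#'   the config, scenario, `dt` and flow law as attributes.
#' @examples
#' traj <- simulate_program(residency_example_config(),
#'                          pandemic_scenario(duration_T = 1), horizon = 10)
#' annual_graduates(traj)
#' @export
simulate_program <- function(config, scenario = pandemic_scenario(),
                             horizon = 10, dt = 0.25,
                             flow = c("conveyor", "first_order")) {
  stopifnot(inherits(config, "program_config"),
            inherits(scenario, "pandemic_scenario"))
  flow <- match.arg(flow)
  if (!is_number(horizon) || horizon <= 0)
    stop_config("'horizon' must be a single positive number")
  if (!is_number(dt) || dt <= 0)
    stop_config("'dt' must be a single positive number")
  if (abs(1 / dt - round(1 / dt)) > 1e-8)
    stop_config("'dt' must divide one year exactly (e.g. 0.25, 0.125, 0.05)")
  n_steps <- round(horizon / dt)
  if (abs(n_steps * dt - horizon) > 1e-8)
    stop_config("'horizon' must be a whole multiple of 'dt'")
  times <- (0:n_steps) * dt

  mat <- switch(flow,
    first_order = .simulate_euler(config, scenario, times, dt),
    conveyor = .simulate_conveyor(config, scenario, times))
  if (any(!is.finite(mat)))
    stop_model("non-finite values during integration: check stage durations and dt")

  df <- data.frame(time = times, mat, check.names = FALSE)
  structure(df,
            class = c("residency_trajectory", "data.frame"),
            config = config, scenario = scenario, dt = dt, flow = flow)
}

.simulate_euler <- function(config, scenario, times, dt) {
  n <- n_stages(config)
  mat <- matrix(NA_real_, length(times), n + 1L,
                dimnames = list(NULL, c(config$stages$name, "graduates_cumulative")))
  state <- list(time = 0, stocks = config$initial_stocks, graduates_cumulative = 0)
  mat[1L, ] <- c(state$stocks, 0)
  for (k in seq_along(times)[-1L]) {
    state <- step_state(state, config, scenario, dt)
    mat[k, ] <- c(state$stocks, state$graduates_cumulative)
  }
  mat
}

# Fixed-duration cohort progression. Cohorts: the initial stock of each
# stage (entering its stage at t = 0) plus annual intake batches at
# t = 1, 2, ... Each cohort's residence in stage i is the stage's
# effective ALOS evaluated at its entry time into that stage.
.simulate_conveyor <- function(config, scenario, times) {
  n <- n_stages(config)
  horizon <- times[length(times)]
  eps <- 1e-9
  n_intakes <- floor(horizon + eps)
  size <- c(config$initial_stocks, rep(config$intake_rate, n_intakes))
  stage0 <- c(seq_len(n), rep(1L, n_intakes))
  t0 <- c(rep(0, n), seq_len(n_intakes))
  keep <- size > 0
  size <- size[keep]; stage0 <- stage0[keep]; t0 <- t0[keep]

  mat <- matrix(0, length(times), n + 1L,
                dimnames = list(NULL, c(config$stages$name, "graduates_cumulative")))
  nominal <- config$stages$nominal_duration
  palos <- config$stages$pandemic_alos
  for (j in seq_along(size)) {
    entry <- t0[j]
    for (i in stage0[j]:n) {
      exit <- entry + .eff_alos(nominal[i], palos[i], scenario, entry)
      in_stage <- times >= entry - eps & times < exit - eps
      mat[in_stage, i] <- mat[in_stage, i] + size[j]
      entry <- exit
    }
    graduated <- times >= entry - eps
    mat[graduated, n + 1L] <- mat[graduated, n + 1L] + size[j]
  }
  mat
}

#' @export
print.residency_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<residency_trajectory> %s flow, T = %.3g yr, horizon %.3g yr, dt %.4g\n",
              attr(x, "flow"), sc$duration_T, x$time[nrow(x)], attr(x, "dt")))
  cat(sprintf("final cumulative graduates: %.3f\n",
              x$graduates_cumulative[nrow(x)]))
  invisible(x)
}

# row indices of whole-year time points 0, 1, ..., floor(horizon)
.year_rows <- function(traj) {
  dt <- attr(traj, "dt")
  per_year <- round(1 / dt)
  n_years <- floor(traj$time[nrow(traj)] + 1e-9)
  1L + (0:n_years) * per_year
}

#' Annual graduate counts of a trajectory
#'
#' First differences of cumulative graduates at whole-year boundaries:
#' element `k` is the number of residents graduating in year `k`, i.e.
#' during `(k-1, k]`.
#'
#' @param traj A trajectory from [simulate_program()] with horizon >= 1.
#' @return Named numeric vector, one element per whole year.
#' @export
annual_graduates <- function(traj) {
  stopifnot(inherits(traj, "residency_trajectory"))
  rows <- .year_rows(traj)
  if (length(rows) < 2L)
    stop_config("trajectory horizon must be at least one year")
  g <- diff(traj$graduates_cumulative[rows])
  names(g) <- paste0("year_", seq_along(g))
  g
}
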