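#' Define one training stage
#'
#' A stage is one accredited year of a residency program (e.g. "R1" or
#' "SR1"). Its `nominal_duration` is the time a resident spends in the
#' stage under normal conditions; `pandemic_alos` is the mean time in the
#' stage while pandemic movement restrictions are active (the average
#' length of stay, ALOS). An ALOS above the nominal duration means
#' residents in that year are delayed; restrictions can never shorten
#' training, so `pandemic_alos >= nominal_duration`.
#'
#' @param name Short stage label, e.g. `"R1"`.
#' @param nominal_duration Baseline time-in-stage in years (> 0).
#' @param pandemic_alos Mean time-in-stage in years while the pandemic
#'   impact is active (>= `nominal_duration`). Defaults to
#'   `nominal_duration` (no impact).
#' @return A `stage_spec` object.
#' @examples
#' stage_spec("SR1", pandemic_alos = 1.32)
#' @export
stage_spec <- function(name, nominal_duration = 1, pandemic_alos = nominal_duration) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("stage 'name' must be a single non-empty string")
  if (!is_number(nominal_duration) || nominal_duration <= 0)
    stop_config(sprintf("stage '%s': 'nominal_duration' must be a positive number", name))
  if (!is_number(pandemic_alos) || pandemic_alos < nominal_duration)
    stop_config(sprintf(
      "stage '%s': 'pandemic_alos' (%s) must be >= 'nominal_duration' (%s); restrictions cannot accelerate training",
      name, format(pandemic_alos), format(nominal_duration)))
  structure(
    list(name = name, nominal_duration = as.numeric(nominal_duration),
         pandemic_alos = as.numeric(pandemic_alos)),
    class = "stage_spec")
}

#' @export
print.stage_spec <- function(x, ...) {
  cat(sprintf("<stage %s> nominal %.2f yr, pandemic ALOS %.2f yr\n",
              x$name, x$nominal_duration, x$pandemic_alos))
  invisible(x)
}

#' Define a training program
#'
#' A program is an ordered chain of stages, the number of residents in
#' each stage at time zero, and an annual intake into the first stage.
#'
#' @param stages List of [stage_spec()] objects, in training order.
#' @param initial_stocks Numeric vector, residents per stage at time 0
#'   (nonnegative, same length as `stages`).
#' @param intake_rate Residents admitted per year into the first stage
#'   (nonnegative). Defaults to the initial stock of the first stage,
#'   consistent with a pre-pandemic equilibrium entry cohort.
#' @return A `program_config` object with a `stages` data frame
#'   (`name`, `nominal_duration`, `pandemic_alos`), `initial_stocks`
#'   and `intake_rate`.
#' @examples
#' program_config(
#'   stages = list(stage_spec("R1", pandemic_alos = 1.22),
#'                 stage_spec("R2", pandemic_alos = 1.08)),
#'   initial_stocks = c(12, 10))
#' @export
program_config <- function(stages, initial_stocks,
                           intake_rate = initial_stocks[[1L]]) {
  if (!is.list(stages) || length(stages) < 1L)
    stop_config("'stages' must be a non-empty list of stage_spec objects")
  if (!all(vapply(stages, inherits, logical(1), "stage_spec")))
    stop_config("every element of 'stages' must be a stage_spec")
  if (!is.numeric(initial_stocks) || length(initial_stocks) != length(stages))
    stop_config(sprintf("'initial_stocks' must be numeric with one entry per stage (%d)",
                        length(stages)))
  if (any(!is.finite(initial_stocks)) || any(initial_stocks < 0))
    stop_config("'initial_stocks' must be finite and nonnegative")
  if (!is_number(intake_rate) || intake_rate < 0)
    stop_config("'intake_rate' must be a single nonnegative number")
  nm <- vapply(stages, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_config("stage names must be unique")
  st <- data.frame(
    name = nm,
    nominal_duration = vapply(stages, `[[`, numeric(1), "nominal_duration"),
    pandemic_alos = vapply(stages, `[[`, numeric(1), "pandemic_alos"),
    stringsAsFactors = FALSE)
  structure(
    list(stages = st, initial_stocks = as.numeric(initial_stocks),
         intake_rate = as.numeric(intake_rate)),
    class = "program_config")
}

#' @export
print.program_config <- function(x, ...) {
  cat(sprintf("<program_config> %d stages, intake %.3g/yr\n",
              nrow(x$stages), x$intake_rate))
  df <- x$stages
  df$initial_stock <- x$initial_stocks
  print(df, row.names = FALSE)
  invisible(x)
}

n_stages <- function(config) nrow(config$stages)

#' Define a pandemic circuit-breaker scenario
#'
#' While the circuit breaker is active (from `onset` for `duration_T`
#' years), each stage's effective ALOS is raised from its nominal
#' duration towards its pandemic ALOS, scaled by `baseline_impact`.
#' When the breaker ends the impact deactivates and progression reverts
#' to nominal. `duration_T = 0` is the business-as-usual (BAU) scenario.
#'
#' @param duration_T Circuit-breaker duration in years (>= 0; 0 = BAU).
#' @param onset Years from simulation start at which the breaker begins
#'   (>= 0, default 0).
#' @param baseline_impact Dimensionless multiplier on the ALOS excess
#'   (`pandemic_alos - nominal_duration`) while active; 1 applies the
#'   calibrated pandemic ALOS as-is, 0 is no impact.
#' @return A `pandemic_scenario` object.
#' @examples
#' pandemic_scenario(duration_T = 1)   # one-year circuit breaker
#' pandemic_scenario(0)                # business as usual
#' @export
pandemic_scenario <- function(duration_T = 0, onset = 0, baseline_impact = 1) {
  if (!is_number(duration_T) || duration_T < 0)
    stop_config("'duration_T' must be a single nonnegative number")
  if (!is_number(onset) || onset < 0)
    stop_config("'onset' must be a single nonnegative number")
  if (!is_number(baseline_impact) || baseline_impact < 0)
    stop_config("'baseline_impact' must be a single nonnegative number")
  structure(
    list(onset = as.numeric(onset), duration_T = as.numeric(duration_T),
         baseline_impact = as.numeric(baseline_impact)),
    class = "pandemic_scenario")
}

#' @export
print.pandemic_scenario <- function(x, ...) {
  if (x$duration_T == 0) {
    cat("<pandemic_scenario> business as usual (T = 0)\n")
  } else {
    cat(sprintf("<pandemic_scenario> onset %.3g yr, T = %.3g yr, baseline impact %.3g\n",
                x$onset, x$duration_T, x$baseline_impact))
  }
  invisible(x)
}

#' Five-year anaesthesiology residency example configuration
#'
#' The bundled example program: the Singapore five-year anaesthesiology
#' residency (junior years R1-R3, senior years SR1-SR2) with the 2020
#' starting batch sizes 12, 10, 10, 18, 12 and per-stage pandemic ALOS
#' values 1.22, 1.08, 1.23, 1.32, 1.23 calibrated from the 2020 circuit
#' breaker, annual intake 12.
#'
#' @return A [program_config()] object.
#' @examples
#' residency_example_config()
#' @export
residency_example_config <- function() {
  alos <- c(R1 = 1.22, R2 = 1.08, R3 = 1.23, SR1 = 1.32, SR2 = 1.23)
  program_config(
    stages = Map(function(nm, a) stage_spec(nm, 1, a), names(alos), alos),
    initial_stocks = c(12, 10, 10, 18, 12),
    intake_rate = 12)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# condition helpers: config/validation errors exit 2 in the CLI,
# model/runtime errors exit 3
stop_config <- function(msg, call. = FALSE) {
  stop(structure(class = c("residflow_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_model <- function(msg) {
  stop(structure(class = c("residflow_model_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
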