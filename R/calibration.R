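DAYS_PER_YEAR <- 365.25

#' Read resident progression records
#'
#' Reads a CSV with one row per resident per training stage and columns
#' `resident_id, stage, entry_date, scheduled_exit, actual_exit`
#' (ISO-8601 dates; `actual_exit` may be empty for residents still in
#' the stage). Malformed dates and violated date ordering are rejected
#' with the offending row numbers.
#'
#' @param path Path to the records CSV.
#' @return Data frame with `Date` columns and character id/stage.
#' @export
read_resident_records <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("records file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("resident_id", "stage", "entry_date", "scheduled_exit", "actual_exit")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_config(sprintf("records file missing column(s): %s",
                        paste(missing, collapse = ", ")))
  parse_col <- function(col, allow_empty = FALSE) {
    x <- trimws(raw[[col]])
    empty <- !nzchar(x)
    d <- as.Date(rep(NA_character_, length(x)))
    d[!empty] <- as.Date(x[!empty], format = "%Y-%m-%d", optional = TRUE)
    bad <- which(!empty & is.na(d))
    if (length(bad))
      stop_config(sprintf("unparseable %s (expect YYYY-MM-DD) in row(s): %s",
                          col, paste(utils::head(bad, 10L), collapse = ", ")))
    if (!allow_empty && any(empty))
      stop_config(sprintf("empty %s in row(s): %s", col,
                          paste(utils::head(which(empty), 10L), collapse = ", ")))
    d
  }
  out <- data.frame(resident_id = raw$resident_id, stage = raw$stage,
                    entry_date = parse_col("entry_date"),
                    scheduled_exit = parse_col("scheduled_exit"),
                    actual_exit = parse_col("actual_exit", allow_empty = TRUE),
                    stringsAsFactors = FALSE)
  bad_order <- which(out$scheduled_exit <= out$entry_date)
  if (length(bad_order))
    stop_config(sprintf("scheduled_exit not after entry_date in row(s): %s",
                        paste(utils::head(bad_order, 10L), collapse = ", ")))
  bad_actual <- which(!is.na(out$actual_exit) & out$actual_exit < out$entry_date)
  if (length(bad_actual))
    stop_config(sprintf("actual_exit before entry_date in row(s): %s",
                        paste(utils::head(bad_actual, 10L), collapse = ", ")))
  out
}

#' Write resident progression records
#'
#' Inverse of [read_resident_records()]: ISO dates, empty string for
#' missing `actual_exit`.
#'
#' @param records Records data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_resident_records <- function(records, path) {
  out <- records
  for (col in c("entry_date", "scheduled_exit", "actual_exit"))
    out[[col]] <- ifelse(is.na(records[[col]]), "",
                         format(records[[col]], "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# per-record completion delay in years (completed records only)
.record_delays <- function(records, allow_early = FALSE) {
  delay <- as.numeric(records$actual_exit - records$scheduled_exit) / DAYS_PER_YEAR
  if (!allow_early) delay <- pmax(0, delay)
  delay
}

#' Average length of stay of one stage, from records
#'
#' The ALOS of a training year is 1 plus the mean completion delay in
#' years over the stage's completed records: a batch with ALOS 1.2
#' needed on average 1.2 years to clear a nominally one-year stage.
#' Records without an actual exit date (residents still in the stage)
#' are excluded with a message; delays are floored at zero unless
#' `allow_early` (training years cannot shrink below nominal).
#'
#' @param records Records data frame (see [read_resident_records()]).
#' @param stage Stage name to calibrate.
#' @param allow_early Permit negative delays (early completion)?
#' @return ALOS in years (>= 1 unless `allow_early`).
#' @examples
#' rec <- data.frame(resident_id = "a", stage = "R2",
#'                   entry_date = as.Date("2019-07-01"),
#'                   scheduled_exit = as.Date("2020-06-30"),
#'                   actual_exit = as.Date("2020-06-30") + 29)
#' alos_from_records(rec, "R2")
#' @export
alos_from_records <- function(records, stage, allow_early = FALSE) {
  sub <- records[records$stage == stage, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_config(sprintf("no records for stage '%s': insufficient data", stage))
  complete <- !is.na(sub$actual_exit)
  if (!any(complete))
    stop_config(sprintf("no completed records for stage '%s': insufficient data", stage))
  if (any(!complete))
    message(sprintf("stage %s: excluding %d incomplete record(s) from ALOS estimation",
                    stage, sum(!complete)))
  1 + mean(.record_delays(sub[complete, , drop = FALSE], allow_early))
}

#' Convert an ALOS to a mean delay in months
#'
#' `(alos - 1) * 12`: an ALOS of 1.08 is a mean delay of about one
#' month; 1.32 is 3.84 months, i.e. more than three months.
#'
#' @param alos ALOS in years; values below 1 produce a warning (they
#'   imply completion faster than nominal).
#' @return Delay in months.
#' @examples
#' delay_months(1.32) # 3.84
#' @export
delay_months <- function(alos) {
  if (!is.numeric(alos)) stop_config("'alos' must be numeric")
  if (any(alos < 1, na.rm = TRUE))
    warning("ALOS below 1 implies faster-than-nominal completion")
  (alos - 1) * 12
}

#' Convert a mean delay in months to an ALOS
#'
#' Exact inverse of [delay_months()]: `1 + months / 12`.
#'
#' @param months Mean delay in months (>= 0 for a valid stage).
#' @return ALOS in years.
#' @export
alos_from_delay <- function(months) {
  if (!is.numeric(months)) stop_config("'months' must be numeric")
  1 + months / 12
}

#' Impact factor of a stage
#'
#' Ratio of the pandemic ALOS to the nominal stage duration; 1 means no
#' impact, 1.32 means a 32% relative extension of the training year.
#'
#' @param pandemic_alos ALOS under restrictions, years.
#' @param nominal Nominal stage duration, years (> 0; default 1).
#' @return Dimensionless ratio.
#' @export
impact_factor <- function(pandemic_alos, nominal = 1) {
  if (!is.numeric(nominal) || any(nominal <= 0))
    stop_config("'nominal' must be positive")
  pandemic_alos / nominal
}

#' Per-stage calibration report
#'
#' Summarises records into one row per stage: record counts, mean
#' completion delay in months, ALOS and impact factor. Stages with no
#' completed records are reported with NA metrics rather than failing.
#'
#' @inheritParams alos_from_records
#' @param nominal Nominal stage duration in years (recycled per stage).
#' @return Data frame with columns `stage`, `n_records`, `n_complete`,
#'   `mean_delay_months`, `alos`, `impact_factor`.
#' @export
calibration_report <- function(records, allow_early = FALSE, nominal = 1) {
  stages <- unique(records$stage)
  nominal <- rep_len(nominal, length(stages))
  rows <- lapply(seq_along(stages), function(k) {
    sub <- records[records$stage == stages[k], , drop = FALSE]
    complete <- !is.na(sub$actual_exit)
    if (!any(complete)) {
      return(data.frame(stage = stages[k], n_records = nrow(sub),
                        n_complete = 0L, mean_delay_months = NA_real_,
                        alos = NA_real_, impact_factor = NA_real_))
    }
    alos <- suppressMessages(alos_from_records(records, stages[k], allow_early))
    data.frame(stage = stages[k], n_records = nrow(sub),
               n_complete = sum(complete),
               mean_delay_months = delay_months(alos),
               alos = alos, impact_factor = impact_factor(alos, nominal[k]))
  })
  do.call(rbind, rows)
}

#' Construct a Delphi response set
#'
#' A respondent-by-variable binary agreement matrix from a Delphi
#' survey round: cell `(r, v)` is 1 when respondent `r` agrees that
#' variable `v` was affected.
#'
#' @param agreement Binary matrix, respondents in rows, variables in
#'   columns.
#' @param variables Variable labels (default: column names).
#' @param respondents Respondent labels (default: row names).
#' @return A `delphi_response_set` object.
#' @export
delphi_response_set <- function(agreement,
                                variables = colnames(agreement),
                                respondents = rownames(agreement)) {
  agreement <- as.matrix(agreement)
  if (nrow(agreement) == 0L)
    stop_config("empty respondent set: invalid survey")
  if (!all(agreement %in% c(0, 1)))
    stop_config("agreement entries must be binary (0/1)")
  if (is.null(variables)) variables <- paste0("V", seq_len(ncol(agreement)))
  if (is.null(respondents)) respondents <- paste0("P", seq_len(nrow(agreement)))
  if (length(variables) != ncol(agreement) || length(respondents) != nrow(agreement))
    stop_config("label lengths must match the agreement matrix dimensions")
  dimnames(agreement) <- list(respondents, variables)
  structure(list(agreement = agreement, variables = as.character(variables),
                 respondents = as.character(respondents)),
            class = "delphi_response_set")
}

#' @export
print.delphi_response_set <- function(x, ...) {
  cat(sprintf("<delphi_response_set> %d respondents x %d variables\n",
              length(x$respondents), length(x$variables)))
  invisible(x)
}

#' Read Delphi survey responses
#'
#' CSV with the respondent id in the first column and one 0/1 column
#' per survey variable.
#'
#' @param path Path to the responses CSV.
#' @return A [delphi_response_set()].
#' @export
read_delphi_responses <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("responses file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2L)
    stop_config("responses file needs a respondent column plus >= 1 variable column")
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat) || !all(mat %in% c(0, 1)))
    stop_config("response cells must be 0 or 1")
  delphi_response_set(mat, variables = colnames(raw)[-1L],
                      respondents = as.character(raw[[1L]]))
}

#' Write Delphi survey responses
#'
#' @param responses A [delphi_response_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_delphi_responses <- function(responses, path) {
  stopifnot(inherits(responses, "delphi_response_set"))
  df <- data.frame(respondent = responses$respondents,
                   responses$agreement, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Delphi consensus variable selection
#'
#' Selects the survey variables whose agreement fraction (agreeing
#' respondents over total respondents) meets or exceeds the consensus
#' threshold, preserving the survey's variable order. Ties at exactly
#' the threshold are included ("at least 80% agreement"): with six
#' respondents and a 0.8 threshold, inclusion requires at least five
#' agreements.
#'
#' @param responses A [delphi_response_set()] or a binary matrix
#'   (respondents x variables).
#' @param threshold Consensus threshold, a fraction in (0, 1]
#'   (default 0.8).
#' @return Character vector of selected variable labels.
#' @examples
#' m <- rbind(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3),
#'            c(1, 0, 0), c(0, 0, 1))
#' colnames(m) <- c("a", "b", "c")
#' delphi_consensus(m) # "a": 5/6 >= 0.8
#' @export
delphi_consensus <- function(responses, threshold = 0.8) {
  if (!inherits(responses, "delphi_response_set"))
    responses <- delphi_response_set(responses)
  if (!is_number(threshold) || threshold <= 0 || threshold > 1)
    stop_config("'threshold' must be a fraction in (0, 1]")
  frac <- colMeans(responses$agreement)
  responses$variables[frac >= threshold - 1e-12]
}
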