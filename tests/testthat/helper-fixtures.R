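# shared fixtures: the bundled five-stage program and small oracles

bundled_program <- function() residency_example_config()

# program with every stage at nominal ALOS (no pandemic effect possible)
neutral_config <- function(n = 5, stock = 12) {
  program_config(
    stages = lapply(seq_len(n), function(i) stage_spec(paste0("S", i))),
    initial_stocks = rep(stock, n),
    intake_rate = stock)
}

# independent brute-force Delphi count: explicit loops, no vectorisation
brute_force_consensus <- function(mat, threshold) {
  selected <- character(0)
  for (v in seq_len(ncol(mat))) {
    agree <- 0L
    for (r in seq_len(nrow(mat))) if (mat[r, v] == 1) agree <- agree + 1L
    if (agree / nrow(mat) >= threshold) selected <- c(selected, colnames(mat)[v])
  }
  selected
}

# records data frame built in code (one row per resident-stage)
make_records <- function(stage, delays_days, entry = as.Date("2019-07-01"),
                         complete = TRUE) {
  scheduled <- entry + 365L
  data.frame(
    resident_id = sprintf("%s-%03d", stage, seq_along(delays_days)),
    stage = stage,
    entry_date = entry,
    scheduled_exit = scheduled,
    actual_exit = if (complete) scheduled + delays_days else as.Date(NA),
    stringsAsFactors = FALSE)
}
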