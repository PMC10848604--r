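Package: residflow
Title: Stock-and-Flow Simulation of Residency Training Pipelines Under
    Pandemic Disruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: System-dynamics simulation of multi-stage medical residency
    training pipelines under pandemic movement restrictions. Models each
    training year as a stock with pandemic-adjusted transfer rates that
    revert when a circuit breaker of duration T ends, under either a
    first-order aging-chain or a fixed-duration (conveyor) flow law.
    Includes scenario grids over circuit-breaker durations, cumulative
    graduate projection, time-to-business-as-usual detection, average
    length of stay (ALOS) calibration from resident-level progression
    records, Delphi consensus counting, and a synthetic record generator
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
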