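# residflow

Stock-and-flow simulation of residency-training pipelines under pandemic
movement restrictions.

When a circuit breaker confines residents to single hospitals, rotations
stall and whole training years take longer than their nominal duration to
complete. Because each training year feeds the next, even a short
disruption depresses specialist output for years after restrictions end.
residflow is for residency program directors and health-workforce planners
who need to quantify that: given a program's structure and the delays one
circuit breaker caused, how many specialists will graduate over the next
five years, and how long until output returns to business as usual (BAU)?

## The model

A program is a chain of training-year stocks $s_1, \dots, s_n$ with annual
intake into $s_1$ and graduation out of $s_n$. Each stage $i$ has a nominal
duration $d_i$ (1 year for a standard program) and a calibrated pandemic
**average length of stay** $a_i \ge d_i$: the mean time a cohort needed to
complete the year under restrictions (ALOS 1.2 = a mean delay of 0.2 years).
A scenario is a circuit breaker of duration $T$ years; while it is active,
progression is governed by the effective ALOS

$$\mathrm{ALOS}_i^{\mathrm{eff}}(t) = d_i + b\,(a_i - d_i), \qquad
  \text{onset} \le t < \text{onset} + T,$$

and by $d_i$ otherwise ($b$ is a baseline-impact multiplier, default 1).
Two flow laws are implemented: fixed-duration cohort progression
(`"conveyor"`, the default — each cohort spends exactly the effective ALOS
in a stage) and a first-order aging chain (`"first_order"` — each stock
drains at $s_i/\mathrm{ALOS}_i^{\mathrm{eff}}$, forward-Euler integrated).
The package also calibrates per-stage ALOS from resident-level progression
records, applies the ≥80% Delphi consensus rule used to select
pandemic-affected training variables, and generates synthetic records with
known ground truth for validation. See the vignette
(`vignettes/residency-pipeline-model.Rmd`) for the full account.

## Worked example

The bundled configuration is a five-year anaesthesiology program (junior
years R1–R3, senior years SR1–SR2) with 2020 starting batches 12, 10, 10,
18, 12, intake 12/year, and circuit-breaker ALOS values calibrated at 1.22,
1.08, 1.23, 1.32, 1.23:

```r
library(residflow)
cfg <- residency_example_config()
grid <- run_scenario_grid(cfg, durations = 0:5, horizon = 12)
grid_report(grid)[, 1:3]
#>   duration_T cumulative_graduates_5yr time_to_bau
#> 1          0                       62           0
#> 2          1                       50           6
#> 3          2                       50           7
#> 4          3                       50           8
#> 5          4                       50           9
#> 6          5                       50          10
```

Reading the table: without a pandemic (T = 0) the program graduates 62
specialists over five years. Any circuit breaker during that window delays
the cohorts in flight and drops the five-year total to 50; a one-year
breaker needs 6 years before annual output rejoins the BAU baseline, and a
four-year breaker needs 9 (recovery is the breaker length plus the 5-year
program: the last cohort admitted under restrictions must clear the whole
pipeline). `time_to_bau()` detects this by requiring annual graduate counts
to stay within 2% of the T = 0 baseline from the reported year onward.

Calibration closes the loop on synthetic records with known ground truth:

```r
rec <- generate_records(record_generator_spec(seed = 1))
calibration_report(rec)
#>   stage n_records n_complete mean_delay_months     alos impact_factor
#> 1    R1       500        500         2.6607967 1.221733      1.221733
#> 2    R2       500        500         0.9661109 1.080509      1.080509
#> 3    R3       500        500         2.7655359 1.230461      1.230461
#> 4   SR1       500        500         3.9315318 1.327628      1.327628
#> 5   SR2       500        500         2.7386612 1.228222      1.228222
```

Every estimated ALOS lands within 0.02 of the generating truth; the R2
delay is about one month and the SR1 delay nearly four — the senior year
whose sub-specialty rotations restrictions hit hardest.

The same workflows are scriptable via `inst/cli/residflow.R`
(`simulate`, `scenarios`, `calibrate`, `delphi`, `synth` subcommands), e.g.

```sh
Rscript inst/cli/residflow.R scenarios \
  --config inst/extdata/program.yaml --out out/ --durations 0,1,2,3,4,5
```

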