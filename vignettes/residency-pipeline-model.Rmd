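---
title: "Modelling residency-training pipelines under pandemic movement restrictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling residency-training pipelines under pandemic movement restrictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residflow)
```

## The problem

Specialist training programs are pipelines: a fixed number of candidates is
admitted each year, progresses through an ordered sequence of accredited
training years, and graduates into the specialist workforce. When a pandemic
circuit breaker confines residents to single institutions, rotations that
require movement between sites stall and whole cohorts take longer than the
nominal year to satisfy their training requirements. Because every training
year feeds the next, a disruption of even one year propagates down the
pipeline for much longer, depressing specialist output well after
restrictions end.

residflow models this as a system-dynamics stock-and-flow system. The
*stocks* are the number of residents in each training year; the *flows* are
the transfer rates between years and the graduation rate out of the final
year. The running example throughout the package is a five-year
anaesthesiology program (junior years R1–R3, senior years SR1–SR2) with
starting batch sizes 12, 10, 10, 18, 12 and an annual intake of 12.

## Average length of stay

The single calibrated quantity per training year is its **average length of
stay (ALOS)**: the mean time, in years, a cohort needs to complete the year.
Under normal conditions the ALOS equals the nominal duration (1.0 for a
standard year); a batch with an ALOS of 1.2 needed on average 1.2 years, a
mean delay of 0.2 years ≈ 2.4 months. `alos_from_records()` estimates it from
resident-level records as

$$\widehat{\mathrm{ALOS}} = 1 + \overline{\max(0,\; t_{\text{actual}} - t_{\text{scheduled}})},$$

with delays measured in days and converted at 365.25 days/year, and records
without an actual exit date excluded. Delays are floored at zero by default
because an accredited training year cannot be completed faster than its
nominal duration; `allow_early = TRUE` lifts the floor for non-standard
programs. The **impact factor** of a stage is defined here as the ratio of
pandemic ALOS to nominal duration (1 = no impact); the term is used loosely
in the health-workforce literature and no formula is standard, so the ratio
definition is a documented interpretation of the package's own.

The bundled calibration, estimated from a 2020 circuit-breaker cohort, is
ALOS 1.22 (R1), 1.08 (R2), 1.23 (R3), 1.32 (SR1) and 1.23 (SR2) — mean
delays from about one month (R2) to nearly four months (SR1).

## The scenario layer

A `pandemic_scenario(duration_T, onset, baseline_impact)` switches each
stage's effective ALOS between two regimes:

$$\mathrm{ALOS}_i^{\mathrm{eff}}(t) = \begin{cases}
d_i + b\,( a_i - d_i) & \text{onset} \le t < \text{onset} + T\\
d_i & \text{otherwise,}
\end{cases}$$

where $d_i$ is the nominal duration, $a_i$ the calibrated pandemic ALOS, $T$
the circuit-breaker duration in years and $b$ the baseline-impact
multiplier. $T = 0$ is the business-as-usual (BAU) reference. The model
assumes delayed residents make up their delay and then progress normally, so
the effective ALOS reverts instantly when the breaker ends — there is no
carried backlog term. $b$ defaults to 1 (apply the calibrated ALOS as-is);
it is exposed because the impact of a future, differently-severe restriction
can be explored by scaling the calibrated excess without re-estimating every
stage.

## Two flow laws

How a stock drains at a given ALOS is a genuine modelling choice, and the
package implements both standard formulations:

* **Fixed-duration progression (`flow = "conveyor"`, the default).**
  Residents move as discrete annual cohorts. A cohort entering stage $i$ at
  time $t$ stays exactly $\mathrm{ALOS}_i^{\mathrm{eff}}(t)$ years; annual
  intake enters as batches of `intake_rate` at whole years. This is the
  conveyor (pipeline-delay) formulation of system dynamics and matches how
  residency actually works: a training year is a scheduled block, not a
  memoryless queue.
* **First-order aging chain (`flow = "first_order"`).** Each stage drains
  continuously at rate $s_i / \mathrm{ALOS}_i^{\mathrm{eff}}(t)$, so the
  mean residence time equals the ALOS but individual residence times are
  exponentially distributed. The system is integrated by forward Euler
  (`step_state()`) with a default step of `dt = 0.25` years; a
  step-refinement test keeps annual outputs within 2% when `dt` is halved,
  and the single-stage case is checked against the closed form
  $s(t) = s_0 e^{-t/\mathrm{ALOS}}$ and an independent ODE solver.

The two laws bracket the plausible behaviour of the real system. They agree
on conservation, on equilibrium throughput (a balanced program graduates its
intake every year), and on the qualitative response to a circuit breaker —
output dips, overshoots while the backlog clears, and rejoins the baseline.
They differ in the *tail*: the conveyor flushes delayed cohorts out in
finite time, while the aging chain recovers along an exponential tail.
That difference is decisive for recovery-time reporting. Under the conveyor
law the recovery time on the bundled program is exactly $T + 5$ years — the
last cohort admitted during the breaker needs its delayed first year plus
four normal years to graduate — giving 6 years for a one-year breaker and 9
years for a four-year breaker. The first-order law stretches the same
recoveries to 7 and 11 years under the default 2% criterion. The conveyor
law is the package default because scheduled, block-structured training is
closer to a fixed delay than to a memoryless queue; the aging chain remains
available for sensitivity analysis and is exercised by the same test suite.

Fractional residents are allowed throughout: stocks are continuous
quantities, and rounding belongs at presentation only (rounding inside the
dynamics would break conservation). No attrition or exam failure is
modelled: every admitted resident eventually graduates, so
$\text{initial total} + \text{intake in} = \text{stocks} + \text{graduates}$
holds identically (with intake counted continuously for the aging chain and
in annual batches for the conveyor); the test suite asserts this to within
1e-6 relative tolerance over randomised programs.

## Scenario grids and time to business as usual

`run_scenario_grid()` simulates one trajectory per circuit-breaker duration
(default $T = 0,\dots,5$ years, horizon 10 years, auto-extended when a
scenario has not recovered within it), always including the $T = 0$
baseline. Two summaries mirror the questions a program director asks:

```{r grid}
cfg <- residency_example_config()
grid <- run_scenario_grid(cfg, durations = 0:5, horizon = 12)
grid_report(grid)[, 1:3]
```

* **Cumulative graduates** over a window (default 5 years):
  `cumulative_graduates()`. Longer breakers never increase it.
* **Time to BAU**: `time_to_bau()` compares a scenario's *annual* graduate
  counts with the baseline's and reports the first whole year from which
  every subsequent year stays within a relative tolerance (default 2%) of
  the baseline. A sustained criterion is used instead of the first crossing
  because recovery overshoots — the backlog clearing — cross the baseline
  years before output actually settles; counting a transient touch would
  understate the disruption. Recovery is reported in whole years because
  annual graduate counts are the decision-relevant unit; when the baseline
  graduates nobody in a year the tolerance falls back to 2% of the
  baseline's mean annual output so the criterion stays defined.

## The synthetic record generator

No resident-level dataset ships with the package, so `generate_records()`
produces records with known ground truth: one row per resident per stage,
scheduled exit one calendar year after entry, and a completion delay drawn
from a zero-truncated normal for residents whose training year overlaps the
pandemic window (zero delay otherwise, the simplest overlap rule). Two
choices matter:

* The truncated normal is parameterised by its **post-truncation mean**: the
  location is solved numerically so that the realised mean delay equals the
  requested `mean_delay_months`. Naive truncation at zero would inflate
  small means (a requested 0.96-month mean with 1-month dispersion would
  realise about 1.26 months) and make parameter recovery fail by more than
  its own sampling error.
* Delays are rounded to whole days, as calendar records would be; at the
  default dispersion of 1 month this adds negligible bias.

The generator's defaults describe the study conditions the package is
validated under: five stages, 500 residents per stage for calibration runs,
mean delays equal to those implied by the bundled ALOS values, a single
cohort entering 2019-07-01 whose training year overlaps the 2020
restriction window. With those defaults, calibration recovers every
per-stage ALOS within 0.02 (about five standard errors at $n = 500$). What
the generator does **not** emulate: correlated delays within institutions,
residents spanning multiple stages with carried-over delays, staggered
entry dates, or partially-affected cohorts — so passing parameter recovery
shows the estimator is consistent under clean conditions, not that real
multi-site records are this well behaved.

`generate_delphi()` plays the same role for the consensus rule: Bernoulli
agreement matrices with per-variable probabilities, against which
`delphi_consensus()` (inclusion when the agreement fraction is at or above
the threshold, ties included — "at least 80%") is checked against
brute-force counting. With six respondents and a 0.8 threshold, inclusion
requires at least five agreements.

## Numerical choices and degenerate inputs

* `dt` must divide one year exactly so annual aggregates are well defined;
  the horizon must be a whole multiple of `dt`.
* Euler stocks are clipped at zero; the clip is unreachable for
  `dt <= min(ALOS)`, which the defaults guarantee.
* Conveyor cohort boundaries use a 1e-9-year tolerance so cohorts landing
  exactly on grid points are counted once.
* A `duration_T = 0` scenario is bitwise identical to a no-pandemic
  configuration under both laws (tested).
* Non-finite values during integration abort with a model error rather than
  propagating.
* Simulation sizes used by the test suite (horizons of 10–25 years,
  dt down to 0.005 for convergence checks, 500–5000 synthetic records) were
  chosen so the whole suite runs in seconds while keeping Monte Carlo
  tolerances at three or more standard errors.

## Known limitations

The model is deterministic and aggregate: it cannot represent
resident-level heterogeneity, institution-specific restriction timing, or
policy feedback (e.g. rotation reshuffling to protect senior residents),
and it assumes all delay is attributable to the movement-restriction window
with full recovery of training capacity the moment it ends. The admission
rate is held constant at its historical value; workforce responses such as
expanded intake after a pandemic are out of scope. Recovery times reported
in whole years inherit a ±1-year sensitivity to the flow-law choice
discussed above, which is why both laws ship.
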