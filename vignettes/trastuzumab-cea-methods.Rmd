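---
title: "Methods: a five-state Markov model for adjuvant trastuzumab in sub-Saharan Africa"
author: "trastcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-state Markov model for adjuvant trastuzumab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The decision problem

Adjuvant trastuzumab roughly halves the hazard of distant recurrence in
early *HER2*-positive breast cancer, but a full course costs on the order
of 20,000 USD even at negotiated prices. Whether that is good value in
sub-Saharan Africa is judged by comparing the incremental
cost-effectiveness ratio (ICER) against WHO-style willingness-to-pay
thresholds of one or three times a country's GDP per capita. `trastcea`
implements the full pipeline for that judgement: a state-transition model
of the disease, discounted accrual of costs and (quality-adjusted) life
years, one-way probabilistic sensitivity analysis, and the inverse
problem — the value-based price at which the treatment would just be
cost-effective.

## Model structure

Patients enter at age 45 (the approximate median age of breast-cancer
diagnosis in the region) in **Remission (R)** after complete resection,
and move monthly among five states:

* **R** — remission; can move to LR, DR, or die of other causes;
* **LR** — loco-regional recurrence; can return to R after successful
  treatment, progress to DR, or die of other causes;
* **DR** — distant (metastatic) recurrence; the only state from which
  **breast-cancer death (BCD)** occurs;
* **BCD** and **D** (other-cause death) — absorbing.

The annual transition probabilities (HERA-trial based) are: R→LR 0.029,
R→DR 0.087, LR→R 0.1, LR→DR 0.261, DR→BCD 0.325. Trastuzumab acts only
on the two transitions *into* DR through a hazard ratio of 0.59, for the
first five years from model entry; DR→BCD is identical in both arms
(the drug delays or prevents metastasis but does not alter its course).
No new recurrences (R→LR, R→DR) occur after 20 years of follow-up;
established disease (LR→DR, DR→BCD) continues to evolve. Cardiotoxicity
is not modelled.

Costs, life years and QALYs are discounted at 3% per year. Utilities are
0.94 (R), 0.82 (LR), 0.58 (DR), 0 when dead.

## Conventions the published description leaves open

Several numerical conventions are not fixed by the published model
description; the package adopts the following, each switchable where it
materially matters, and logs the resolved choices in a run manifest:

* **Period basis of the transition probabilities.** The probabilities
  above are read as *annual* and converted to the monthly cycle with the
  constant-hazard form `p_m = 1 − (1 − p_a)^(1/12)`. Reading 0.325 as a
  *monthly* DR→BCD probability would imply a median metastatic survival
  under two months, which is clinically implausible; the annual reading
  is therefore adopted.
* **Hazard-ratio scale.** Hazard ratios act on hazards, so the effect is
  applied on the rate scale, `p' = 1 − (1 − p)^hr`, never by multiplying
  probabilities. The effect window is cycles 0–59 inclusive; the clock is
  calendar time from model entry and is not reset by LR→R transitions.
* **Competing risks within a cycle.** Other-cause death (from the life
  table) is applied first; the disease transition probabilities act on
  the surviving mass. Alternative orderings change results in the third
  decimal and are one reason reproduction tolerances are quoted at ±5%.
* **Life-table conversion.** Five-year death probabilities are converted
  assuming a constant hazard within each band
  (`p_m = 1 − (1 − q5)^(1/60)`), held piecewise constant in age
  (half-open bands `[x, x+5)`), and clamped to the terminal band beyond
  the table so old-age hazards never vanish.
* **State-cost accrual.** The recurrence-state costs are *annual*
  management costs accrued pro rata per cycle in state (`per_cycle`
  mode, the default). Charging them per monthly cycle at face value
  would produce arm costs an order of magnitude above the published
  ones, so the annual-rate reading is the only one consistent with the
  published totals; a `per_episode` mode (full amount once per entry
  into the state) is provided as the alternative interpretation, and is
  the largest single contributor to the reproduction tolerance.
* **Treatment-cost timing.** The course cost is spread uniformly over
  the first 12 monthly cycles and discounted (treatment runs about a
  year), giving a discounted course cost of ~19,728 USD per 20,000 USD
  list price; an `upfront` (undiscounted lump-sum) switch reproduces
  published incremental costs slightly more closely and is available in
  the configuration.
* **Half-cycle correction.** Off by default (occupancy at cycle start);
  a trapezoidal correction is available via
  `model_params(half_cycle_correction = TRUE)`.

## Numerical choices

The trace starts from full occupancy of R and stops when living occupancy
falls below `epsilon = 1e-8` or the age cap of 110 years is reached
(780 monthly cycles from entry at 45). Residual living mass at the cap is
truncated; it is flagged with a warning only when it exceeds `1e-4` of
the cohort, below which its effect on discounted life years is smaller
than `5e-4` years and immaterial at the reported precision. Transition
matrices are validated to row-sum to 1 within `1e-12`, and traces
conserve mass within `1e-10`. In the microsimulation, next states are
sampled by inverting the cumulative transition probabilities in the
fixed state order (R, LR, DR, BCD, D), and each arm receives its own
deterministic seed substream derived from the master seed and the arm
label, so results are bit-reproducible and independent of evaluation
order.

## Background mortality and the surrogate life tables

Country life tables enter as CSV files of five-year death probabilities
(`age_start,age_end,q5`). The WHO per-country tables used by the original
analysis are not redistributed with the package, so the built-in
reference scenarios use **surrogate** Gompertz life tables: hazard
`a·exp(b·t)` with slope `b = 0.09`/yr (a typical adult-mortality slope)
and level `a` solved so that remaining life expectancy at age 45 matches
approximate national values for women around 2016, chosen once from
public summary statistics and rounded to the nearest year:

| Country | e(45) target | Country | e(45) target |
|---|---|---|---|
| Congo | 29 | Nigeria | 26 |
| Ethiopia | 31 | Rwanda | 31 |
| Guinea | 28 | Uganda | 29 |
| Kenya | 31 | Zambia | 29 |
| Namibia | 30 | Zimbabwe | 28 |
| South Africa | 29 | | |

Surrogate tables are labelled as such in their `country` attribute and
are only ever produced by an explicit call to `surrogate_life_table()`;
a user-supplied table passed to `reference_scenario()` is used verbatim.
A Gompertz law calibrated to one summary statistic understates child and
young-adult mortality (irrelevant here, since the model starts at 45)
and smooths HIV-era excess adult mortality; with the recurrence process
dominating survival, the base-case ICERs are only mildly sensitive to
this approximation, but per-country life-year levels can differ from
analyses run on the real WHO tables by a few percent.

## What the synthetic-data generator does and does not emulate

`random_scenario()` draws a complete country scenario: Gompertz slope
uniform on (0.08, 0.105), life expectancy at 45 uniform on (24, 34)
years, local-recurrence cost log-uniform across the span of the
published country costs (900–12,000 USD/yr), a distant/local cost ratio
on (1.2, 1.6) — every published country shows distant ≥ local — and GDP
per capita log-uniform on (400, 6,000) USD. This exercises the pipeline
across realistic input ranges; it does not emulate HER2-incidence
epidemiology, patient-level covariates, or correlated cost structures,
so passing property tests on synthetic scenarios demonstrates
correctness of the computation, not calibration to any particular
country's data.

## Sensitivity analysis

The one-way PSA redraws one parameter at a time, holding all others at
base case: utilities and transition probabilities from their Beta
distributions, the hazard ratio from Log-normal(−0.527, 0.089)
(interpreted as mean and SD of the log; its median exp(−0.527) ≈ 0.59
equals the base-case hazard ratio). Several of the published Beta shapes
are not centred on their point estimates (e.g. Beta(77, 23) with point
estimate 0.82, Beta(119, 931) with 0.261); they are sampled exactly as
given, without rescaling, and the discrepancy is simply inherited. Two
varied inputs have no published distribution and carry package defaults
that are *not* source-derived: the discount rate, uniform over
{0%, 3%, 6%}, and the course cost, Gamma with mean 20,000 and SD 2,000
USD. Draws with non-positive incremental QALYs are counted and reported
as undefined rather than dropped. Parameters that do not alter the
transition process (costs, utilities, discount rate) reuse the base-case
traces and only re-accrue, which makes those sweeps essentially free.
Each parameter draws from its own substream (a stable hash of the
parameter name combined with the master seed), so adding or reordering
parameters leaves the others' draws unchanged. The default is 1,000
draws per parameter; the package's own test suite uses 10–80 draws per
parameter, which is ample for the rank and monotonicity properties it
checks.

## Value-based pricing

The transition process does not depend on the drug price, so incremental
discounted cost is affine in the course price,
`Δcost(price) = a·price + b`, with `a` the discounted schedule value of
one price unit and `b` the price-independent difference in state costs.
The value-based price at threshold `wtp` is therefore exact:
`price = (wtp·ΔQALY − b) / a`, clipped at zero (with a flag) when even a
free drug exceeds the threshold. A bisection fallback that re-evaluates
the full accrual verifies the closed form to 1e-6 relative; re-running
the whole model at the solved price reproduces the threshold ICER to
within 0.01%.

## Problem sizes and reproducibility

A lifetime cohort trace is 780 monthly cycles and runs in ~25 ms; the
package's reference analyses therefore use full lifetime horizons
throughout. Microsimulation summaries in the documentation and
acceptance analyses use 10,000 patients per arm (the size of the
original hypothetical cohort; SE of mean LYs ≈ 0.055) and 100,000
patients where the cohort trace is verified as the microsimulation's
expectation. All stochastic components (microsimulation, PSA, synthetic
scenarios) are driven by explicit integer seeds with deterministic
substreams.

## Known limitations

* The five-state structure has no tunnel states: time-in-state effects
  (e.g. declining DR mortality with time since metastasis) cannot be
  represented.
* The treatment-effect window is a sharp on/off at five years.
* Indirect and chemotherapy costs are excluded (identical in both arms);
  HER2 testing costs are not modelled.
* Surrogate life tables approximate, and cannot replace, the WHO
  country tables (see above); base-case reproductions quoted in the
  README use them and inherit a few percent of tolerance from that
  substitution and from the open conventions listed earlier.
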