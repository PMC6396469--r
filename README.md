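# trastcea

Cost-effectiveness analysis of adjuvant trastuzumab for early
*HER2*-positive breast cancer in eleven sub-Saharan African countries,
as a tested, reusable R pipeline.

Trastuzumab substantially reduces distant recurrence in *HER2*-positive
early breast cancer, but a full adjuvant course costs ~20,000 USD even at
negotiated prices. `trastcea` asks, country by country, whether that is
good value at WHO-style willingness-to-pay (WTP) thresholds of 1× or 3×
GDP per capita — and, since the answer is generally *no*, what the drug
*should* cost: the value-based price (VBP) at which it would just be
cost-effective.

## The model

A five-state state-transition (Markov) model with monthly cycles and a
lifetime horizon. Patients enter in remission (R) at age 45 and move among
R, loco-regional recurrence (LR), distant recurrence (DR), breast-cancer
death (BCD, reachable only from DR) and other-cause death (D, from any
living state, driven by a country life table of 5-year death
probabilities q₅ converted to monthly hazards).

Annual transition probabilities (converted to monthly via
p_m = 1 − (1 − p_a)^(1/12)):

| transition | R→LR | R→DR | LR→R | LR→DR | DR→BCD |
|---|---|---|---|---|---|
| annual p | 0.029 | 0.087 | 0.1 | 0.261 | 0.325 |

Trastuzumab applies a hazard ratio HR = 0.59 to the two transitions into
DR, on the rate scale (p′ = 1 − (1 − p)^HR), for the first 5 years; no
new recurrences occur after 20 years. Utilities: R 0.94, LR 0.82,
DR 0.58. Costs, life years (LY) and QALYs are discounted at 3%/yr, and

ICER = (Cost_tz − Cost_ctrl) / (QALY_tz − QALY_ctrl)   [USD/QALY].

The model runs both as a deterministic cohort trace and as an
individual-level microsimulation (default 10,000 patients/arm) sampled
from the same transition matrices; a one-way probabilistic sensitivity
analysis varies each parameter from its Beta/log-normal distribution; and
the VBP solver inverts the affine price→cost relationship exactly. See
`vignettes/trastuzumab-cea-methods.Rmd` for every modelling convention.

## Worked example

```r
library(trastcea)

sc  <- reference_scenario("South Africa")   # published costs + surrogate life table
res <- run_cea(model_params(), sc$life_table, sc$costs, label = sc$country)
res
#> <cea_result> South Africa ( cohort mode )
#>   trastuzumab  LY   9.88  QALY   8.68  cost      50983 USD
#>   control      LY   8.88  QALY   7.71  cost      31930 USD
#>   increments   LY   1.00  QALY   0.97  cost      19053 USD
#>   ICER 19697 (more costly, more effective) USD/QALY | 19113 (more costly, more effective) USD/LY
```

Treatment buys about one discounted life year (0.97 QALYs) for ~19,000
USD extra, an ICER of ~19,700 USD/QALY — more than three times South
Africa's GDP per capita, i.e. not cost-effective at WHO thresholds. The
value-based price at a 1× GDP-per-capita threshold:

```r
solve_vbp(model_params(), sc$life_table, sc$costs,
          wtp = sc$gdp_per_capita, wtp_multiple = 1, label = sc$country)
#> <vbp_result> South Africa
#>   WTP 5750 USD/QALY (1x GDP per capita) -> course price 6325 USD (ICER 5750)
```

The course would need to cost ≲ 6,300 USD (vs 20,000) to be
cost-effective there. Other entry points: `run_all_countries()` for the
full 11-country table, `one_way_psa()` for sensitivity analysis,
`run_microsim()` for patient-level runs with standard errors,
`read_run_config()`/`run_base_case()` for YAML-driven, manifest-logged
runs, and `read_life_table()` to supply real WHO life tables in place of
the built-in Gompertz surrogates.

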