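Package: trastcea
Title: Cost-Effectiveness of Adjuvant Trastuzumab in Sub-Saharan Africa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state monthly-cycle Markov state-transition model of
    adjuvant trastuzumab for early HER2-positive breast cancer in eleven
    sub-Saharan African countries, run either as a deterministic cohort
    trace or as an individual-level microsimulation. Accrues discounted
    costs, life years and quality-adjusted life years, computes incremental
    cost-effectiveness ratios, performs one-way probabilistic sensitivity
    analysis with Beta and log-normal parameter distributions, and inverts
    the model to obtain value-based prices against GDP-per-capita
    willingness-to-pay thresholds. Country background mortality enters as
    five-year life-table death probabilities; a synthetic-scenario
    generator (Gompertz life tables, cost and GDP draws) makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
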