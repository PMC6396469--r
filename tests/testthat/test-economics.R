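test_that("dosing arithmetic matches the published schedule", {
  expect_equal(dose_total_mg(60, wastage = 0), 8 * 60 + 16 * 6 * 60)  # 6240
  expect_equal(dose_total_mg(60), 6240 * 1.10)                        # 6864
  expect_error(dose_total_mg(0), "positive")
  expect_error(dose_total_mg(-5), "positive")
  expect_error(dose_total_mg(60, wastage = 1), "\\[0, 1\\)")
})

test_that("discount factors follow the annual compounding convention", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-14)
  expect_identical(discount_factor(0:100, 0), rep(1, 101))
  expect_true(all(diff(discount_factor(0:50, 0.03)) < 0))
  expect_error(discount_factor(1, -0.1), ">= 0")
})

test_that("the treatment cost schedule discounts the spread instalments", {
  # rate 0: both modes return the course cost exactly
  expect_equal(treatment_cost_schedule(20000, 0, "spread"), 20000)
  expect_equal(treatment_cost_schedule(20000, 0, "upfront"), 20000)
  expect_equal(treatment_cost_schedule(20000, 0.03, "upfront"), 20000)
  # spread mode: geometric sum evaluated independently
  r <- 1.03^(-1 / 12)
  expect_equal(treatment_cost_schedule(20000, 0.03, "spread"),
               (20000 / 12) * (1 - r^12) / (1 - r), tolerance = 1e-12)
  # the schedule is linear in the course cost (the value-based-price slope)
  expect_equal(treatment_cost_schedule(20000, 0.03),
               20000 * treatment_cost_schedule(1, 0.03), tolerance = 1e-9)
})

test_that("accrual reproduces closed forms on degenerate traces", {
  # immortal all-remission cohort over a 10-year horizon
  tr <- suppressWarnings(
    run_cohort(no_disease_params(start_age = 45, max_age = 55),
               immortal_life_table(), "control"))
  got <- accrue(tr, cost_inputs(), utilities(), annual_rate = 0)
  expect_equal(got$ly, 10, tolerance = 1e-12)
  expect_equal(got$qaly, 9.4, tolerance = 1e-12)   # 10 years at utility 0.94
  expect_equal(got$cost, 0)
  # zero utilities kill the QALYs regardless of the trace
  got0 <- accrue(tr, cost_inputs(), utilities(0, 0, 0), annual_rate = 0)
  expect_equal(got0$qaly, 0)
  # discounting can only shrink outcomes
  gotd <- accrue(tr, cost_inputs(), utilities(), annual_rate = 0.03)
  expect_lt(gotd$ly, got$ly)
  expect_lt(gotd$qaly, got$qaly)
})

test_that("state costs are linear and QALYs never exceed LYs", {
  lt <- flat_life_table(0.05)
  tr <- run_cohort(model_params(), lt, "control")
  c1 <- cost_inputs(0, 0, 974, 1356)
  c2 <- cost_inputs(0, 0, 2 * 974, 2 * 1356)
  a1 <- accrue(tr, c1)
  a2 <- accrue(tr, c2)
  expect_equal(a2$cost, 2 * a1$cost, tolerance = 1e-12)
  expect_lt(a1$qaly, a1$ly)
})

test_that("per-episode accrual charges each entry once", {
  # deterministic single transition: R -> DR in the first cycle
  p <- model_params(p_R_LR = 0, p_R_DR = 1, p_LR_R = 0, p_LR_DR = 0,
                    p_DR_BCD = 0, start_age = 45, max_age = 55)
  tr <- suppressWarnings(run_cohort(p, immortal_life_table(), "control"))
  costs <- cost_inputs(0, 0, 500, 1000, accrual_mode = "per_episode")
  got <- accrue(tr, costs, annual_rate = 0)
  # everyone enters DR exactly once, never LR
  expect_equal(got$cost, 1000, tolerance = 1e-9)
})

test_that("ICERs divide increments and label the quadrants", {
  # printed-precision increments: Congo's rounded inputs
  ic <- icer(19997, 0.97, 0, 0)
  expect_equal(ic$value, 19997 / 0.97, tolerance = 1e-12)
  expect_equal(ic$value, 20616, tolerance = 1e-4)
  expect_equal(ic$quadrant, "more costly, more effective")
  expect_equal(icer(5000, 2, 5000, 1)$value, 0)
  expect_equal(icer(2000, 1, 1000, 2)$quadrant, "dominated")
  expect_equal(icer(1000, 2, 2000, 1)$quadrant, "dominant")
  expect_equal(icer(1000, 1, 2000, 2)$quadrant, "less costly, less effective")
  un <- icer(1000, 1, 500, 1)
  expect_equal(un$quadrant, "undefined")
  expect_true(is.na(un$value))
  # adding a constant cost to both strategies leaves the ICER unchanged
  expect_equal(icer(1000 + 777, 2, 500 + 777, 1)$value,
               icer(1000, 2, 500, 1)$value)
})

test_that("with hr = 1 and no state costs the arms differ only by drug cost", {
  lt <- flat_life_table(0.05)
  p <- model_params(hazard_ratio = 1)
  costs <- cost_inputs(20000, 0, 0, 0)
  res <- run_cea(p, lt, costs)
  expect_equal(res$d_ly, 0, tolerance = 1e-12)
  expect_equal(res$d_qaly, 0, tolerance = 1e-12)
  expect_equal(res$d_cost, treatment_cost_schedule(20000, 0.03),
               tolerance = 1e-9)
  expect_equal(res$icer_qaly$quadrant, "undefined")
})

test_that("half-cycle correction shifts accruals by less than one cycle", {
  lt <- flat_life_table(0.05)
  plain <- accrue(run_cohort(model_params(), lt, "control"))
  hcc <- accrue(run_cohort(model_params(half_cycle_correction = TRUE),
                           lt, "control"))
  expect_false(identical(plain$ly, hcc$ly))
  expect_lt(abs(plain$ly - hcc$ly), 1 / 12)
})
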