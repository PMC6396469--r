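test_that("annual-to-cycle conversion follows the constant-hazard form", {
  expect_identical(annual_to_cycle(0, 12), 0)
  expect_equal(annual_to_cycle(0.5, 1), 0.5)
  expect_identical(annual_to_cycle(1, 12), 1)
  # closed form cross-checked via the rate route
  expect_equal(annual_to_cycle(0.087, 12), 1 - exp(log(1 - 0.087) / 12),
               tolerance = 1e-14)
  expect_equal(annual_to_cycle(0.087, 12), 0.0075556, tolerance = 1e-4)
  expect_error(annual_to_cycle(1.2), "\\[0, 1\\]")
})

test_that("hazard ratios act on the rate scale", {
  expect_equal(apply_hazard_ratio(0.3, 1), 0.3)
  expect_identical(apply_hazard_ratio(0, 0.59), 0)
  p <- annual_to_cycle(0.087, 12)
  # cross-check: r = -log(1-p); p' = 1 - exp(-hr * r)
  expect_equal(apply_hazard_ratio(p, 0.59), 1 - exp(-0.59 * -log(1 - p)),
               tolerance = 1e-14)
  expect_equal(apply_hazard_ratio(p, 0.59), 0.0044655, tolerance = 1e-4)
  expect_error(apply_hazard_ratio(1, 0.5), "\\[0, 1\\)")
  expect_error(apply_hazard_ratio(0.5, 0), "> 0")
})

test_that("transition matrices are stochastic and respect the state graph", {
  lt <- flat_life_table(0.05)
  p <- model_params()
  for (cyc in c(0L, 59L, 60L, 150L, 240L, 600L)) {
    for (arm in c("trastuzumab", "control")) {
      M <- build_transition_matrix(p, lt, cyc, arm)
      expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
      # forbidden transitions carry no mass
      expect_identical(M["R", "BCD"], 0)
      expect_identical(M["LR", "BCD"], 0)
      expect_identical(M["DR", "R"], 0)
      expect_identical(M["DR", "LR"], 0)
      expect_identical(M["BCD", "BCD"], 1)
      expect_identical(M["D", "D"], 1)
      expect_identical(unname(M["BCD", -4]), rep(0, 4))
    }
  }
})

test_that("the treatment effect is confined to its arm, window and edges", {
  lt <- flat_life_table(0.05)
  p <- model_params()
  M_tz0 <- build_transition_matrix(p, lt, 0, "trastuzumab")
  M_ct0 <- build_transition_matrix(p, lt, 0, "control")
  expect_lt(M_tz0["R", "DR"], M_ct0["R", "DR"])
  expect_lt(M_tz0["LR", "DR"], M_ct0["LR", "DR"])
  # DR -> BCD identical across arms
  expect_identical(M_tz0["DR", "BCD"], M_ct0["DR", "BCD"])
  # effect window is cycles 0..59: gone from cycle 60
  M_tz60 <- build_transition_matrix(p, lt, 60, "trastuzumab")
  M_ct60 <- build_transition_matrix(p, lt, 60, "control")
  expect_identical(M_tz60, M_ct60)
  # hr = 1 collapses the arms at every cycle
  p1 <- model_params(hazard_ratio = 1)
  for (cyc in c(0L, 30L, 59L)) {
    expect_identical(build_transition_matrix(p1, lt, cyc, "trastuzumab"),
                     build_transition_matrix(p1, lt, cyc, "control"))
  }
})

test_that("no new recurrences occur after the 20-year cutoff", {
  lt <- flat_life_table(0.05)
  p <- model_params()
  M <- build_transition_matrix(p, lt, 240, "control")
  expect_identical(M["R", "LR"], 0)
  expect_identical(M["R", "DR"], 0)
  # established disease still evolves
  expect_gt(M["LR", "DR"], 0)
  expect_gt(M["DR", "BCD"], 0)
  M239 <- build_transition_matrix(p, lt, 239, "control")
  expect_gt(M239["R", "DR"], 0)
})

test_that("cohort traces conserve mass and absorb monotonically", {
  lt <- flat_life_table(0.05)
  for (arm in c("trastuzumab", "control")) {
    tr <- run_cohort(model_params(), lt, arm)
    expect_lt(max(abs(rowSums(tr) - 1)), 1e-10)
    expect_identical(unname(tr[1, ]), c(1, 0, 0, 0, 0))
    expect_true(all(diff(tr[, "BCD"]) >= 0))
    expect_true(all(diff(tr[, "D"]) >= 0))
    expect_lt(sum(tr[nrow(tr), 1:3]), 1e-8)
  }
})

test_that("a disease-free immortal cohort stays in remission forever", {
  tr <- suppressWarnings(
    run_cohort(no_disease_params(start_age = 45, max_age = 55),
               immortal_life_table(), "control"))
  expect_true(all(tr[, "R"] == 1))
})

test_that("a certain per-cycle progression empties distant recurrence", {
  # annual DR->BCD of 1 converts to a per-cycle probability of 1
  p <- fast_params(p_DR_BCD = 1, p_R_DR = 0.5)
  tr <- suppressWarnings(run_cohort(p, immortal_life_table(), "control"))
  # whatever enters DR at cycle t has fully left for BCD by t + 1
  entered <- attr(tr, "entries")[, "DR"]
  stayed <- tr[-1, "DR"]
  expect_equal(stayed, entered, tolerance = 1e-12)
})

test_that("protection accumulates: fewer distant recurrences under hr < 1", {
  lt <- flat_life_table(0.05)
  tz <- run_cohort(model_params(), lt, "trastuzumab")
  ct <- run_cohort(model_params(), lt, "control")
  n <- min(nrow(tz), nrow(ct)) - 1L
  cum_tz <- cumsum(attr(tz, "entries")[seq_len(n), "DR"])
  cum_ct <- cumsum(attr(ct, "entries")[seq_len(n), "DR"])
  expect_true(all(cum_tz <= cum_ct + 1e-12))
})

test_that("raising any transition into distant recurrence lowers life years", {
  lt <- flat_life_table(0.05)
  base <- accrue(run_cohort(model_params(), lt, "control"))$ly
  up_r <- accrue(run_cohort(model_params(p_R_DR = 0.2), lt, "control"))$ly
  up_lr <- accrue(run_cohort(model_params(p_LR_DR = 0.5), lt, "control"))$ly
  expect_lt(up_r, base)
  expect_lt(up_lr, base)
})

test_that("microsimulation is seed-reproducible and matches its expectation", {
  lt <- flat_life_table(0.05)
  p <- model_params()
  a <- run_microsim(p, lt, "control", n_patients = 500, seed = 42)
  b <- run_microsim(p, lt, "control", n_patients = 500, seed = 42)
  expect_identical(a$summary, b$summary)
  c_ <- run_microsim(p, lt, "control", n_patients = 500, seed = 43)
  expect_false(identical(a$summary, c_$summary))

  # cohort trace is the microsimulation's expectation
  costs <- cost_inputs(20000, 0, 974, 1356)
  ms <- run_microsim(p, lt, "control", n_patients = 20000, seed = 7,
                     costs = costs)
  coh <- accrue(run_cohort(p, lt, "control"), costs)
  expect_lt(abs(ms$summary$mean[1] - coh$ly), 3 * ms$summary$se[1])
  expect_lt(abs(ms$summary$mean[2] - coh$qaly), 3 * ms$summary$se[2])
  expect_lt(abs(ms$summary$mean[3] - coh$cost), 3 * ms$summary$se[3])
})

test_that("a single untreatable immortal patient never leaves remission", {
  ms <- run_microsim(no_disease_params(start_age = 45, max_age = 50),
                     immortal_life_table(), "control",
                     n_patients = 1, seed = 1, keep_paths = TRUE)
  expect_true(all(ms$paths == 1L))
})

test_that("trace CSV export round-trips", {
  tr <- suppressWarnings(   # short horizon: truncation at the cap is expected
    run_cohort(fast_params(), flat_life_table(0.2), "control"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_identical(names(back), c("cycle", "age", "R", "LR", "DR", "BCD", "D"))
  expect_equal(as.matrix(back[, 3:7]), unclass(tr)[, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})
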