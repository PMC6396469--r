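#' Total trastuzumab dose requirement
#'
#' Total milligrams for a full adjuvant course: one loading dose followed
#' by maintenance doses (the standard 3-weekly schedule is 8 mg/kg loading
#' then sixteen doses of 6 mg/kg over ~12 months), inflated by a drug
#' wastage fraction for partially used vials.
#'
#' @param weight Patient weight in kg; must be positive.
#' @param loading Loading dose, mg/kg (default 8).
#' @param maintenance Maintenance dose, mg/kg (default 6).
#' @param n_maintenance Number of maintenance administrations (default 16).
#' @param wastage Wastage fraction in `[0, 1)` (default 0.10).
#' @return Total dose in mg.
#' @export
#' @examples
#' dose_total_mg(60)                # 6,864 mg with 10% wastage
#' dose_total_mg(60, wastage = 0)   # 6,240 mg
dose_total_mg <- function(weight, loading = 8, maintenance = 6,
                          n_maintenance = 16, wastage = 0.10) {
  if (!is.numeric(weight) || any(weight <= 0)) {
    stop("weight must be positive", call. = FALSE)
  }
  if (any(wastage < 0 | wastage >= 1)) {
    stop("wastage must lie in [0, 1)", call. = FALSE)
  }
  (loading * weight + n_maintenance * maintenance * weight) * (1 + wastage)
}

#' Discount factor for a model cycle
#'
#' `(1 + annual_rate)^(-cycle_index / cycles_per_year)`: cycle 0 is
#' undiscounted, and a zero rate gives 1 for every cycle.
#'
#' @param cycle_index Zero-based cycle index; vectorised.
#' @param annual_rate Annual discount rate, e.g. 0.03.
#' @param cycles_per_year Cycles per year (default 12).
#' @return Dimensionless discount factor(s).
#' @export
discount_factor <- function(cycle_index, annual_rate = 0.03,
                            cycles_per_year = 12) {
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Discounted cost of the trastuzumab course
#'
#' The course cost is either spread uniformly over the first year of
#' monthly cycles (treatment is administered over ~12 months) and each
#' instalment discounted, or charged as an undiscounted lump sum at entry.
#'
#' @param course_cost Full course cost, USD.
#' @param annual_rate Annual discount rate.
#' @param mode `"spread"` (default) or `"upfront"`.
#' @param cycles_per_year Cycles per year.
#' @param n_cycles Number of cycles the spread covers (default one year).
#' @return Discounted course cost, USD.
#' @export
treatment_cost_schedule <- function(course_cost, annual_rate = 0.03,
                                    mode = c("spread", "upfront"),
                                    cycles_per_year = 12,
                                    n_cycles = cycles_per_year) {
  mode <- match.arg(mode)
  if (course_cost < 0) stop("course_cost must be >= 0", call. = FALSE)
  if (mode == "upfront") return(course_cost)
  inst <- course_cost / n_cycles
  sum(inst * discount_factor(0:(n_cycles - 1L), annual_rate, cycles_per_year))
}

#' Accrue discounted outcomes over a cohort trace
#'
#' Sums discounted life years, QALYs and costs over the trace. Each cycle
#' contributes `1 / cycles_per_year` years for the living states (R, LR,
#' DR), weighted by the state utility for QALYs, all discounted at the
#' cycle's factor. State costs accrue either pro rata per cycle in state
#' (`per_cycle`, treating `cost_LR`/`cost_DR` as annual rates) or once per
#' entry into the state (`per_episode`, using the trace's recorded
#' inflows). The trastuzumab arm additionally accrues the course cost via
#' [treatment_cost_schedule()]. A half-cycle correction (if the trace was
#' built with one) replaces start-of-cycle occupancy by the trapezoidal
#' average of adjacent cycles.
#'
#' @param trace A [run_cohort()] trace.
#' @param costs A [cost_inputs()].
#' @param utils_ A [utilities()].
#' @param annual_rate Annual discount rate (default 0.03).
#' @return A list with components `ly`, `qaly`, `cost` (discounted).
#' @export
accrue <- function(trace, costs = cost_inputs(), utils_ = utilities(),
                   annual_rate = 0.03) {
  stopifnot(inherits(trace, "cohort_trace"))
  cpy <- attr(trace, "cycles_per_year")
  t_total <- nrow(trace) - 1L            # trace rows are cycles 0..T
  occ <- unclass(trace)
  if (isTRUE(attr(trace, "half_cycle_correction"))) {
    occ <- (occ[-nrow(occ), , drop = FALSE] + occ[-1L, , drop = FALSE]) / 2
  } else {
    occ <- occ[seq_len(t_total), , drop = FALSE]
  }
  df <- discount_factor(seq_len(t_total) - 1L, annual_rate, cpy)
  living <- occ[, "R"] + occ[, "LR"] + occ[, "DR"]
  ly <- sum(df * living) / cpy
  qaly <- sum(df * (occ[, "R"] * utils_$u_R + occ[, "LR"] * utils_$u_LR +
                      occ[, "DR"] * utils_$u_DR)) / cpy
  state_cost <- if (costs$accrual_mode == "per_cycle") {
    sum(df * (occ[, "R"] * costs$cost_R + occ[, "LR"] * costs$cost_LR +
                occ[, "DR"] * costs$cost_DR)) / cpy
  } else {
    ent <- attr(trace, "entries")
    # entries during cycle t are realised (and discounted) at cycle t + 1
    df_next <- discount_factor(seq_len(t_total), annual_rate, cpy)
    sum(df_next * (ent[, "LR"] * costs$cost_LR + ent[, "DR"] * costs$cost_DR))
  }
  treat <- if (attr(trace, "arm") == "trastuzumab") {
    treatment_cost_schedule(costs$trastuzumab_course_cost,
                            annual_rate = annual_rate,
                            mode = costs$treatment_cost_mode,
                            cycles_per_year = cpy)
  } else 0
  list(ly = ly, qaly = qaly, cost = state_cost + treat)
}

#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' Computes `(cost_new - cost_ref) / (effect_new - effect_ref)` and labels
#' the cost-effectiveness quadrant rather than silently returning a
#' number when the ratio is not meaningful: a strategy that costs more
#' and is less effective is `"dominated"`, one that costs less and is
#' more effective is `"dominant"`, and a zero effect difference makes the
#' ICER `"undefined"` (value `NA`).
#'
#' @param cost_new,effect_new Cost and effect of the evaluated strategy.
#' @param cost_ref,effect_ref Cost and effect of the comparator.
#' @return An object of class `icer_result`: list with `value` (USD per
#'   effect unit, `NA` if undefined), `quadrant`, and the increments
#'   `d_cost`, `d_effect`.
#' @export
#' @examples
#' icer(22585, 8.69, 2588, 7.72)
icer <- function(cost_new, effect_new, cost_ref, effect_ref) {
  d_cost <- cost_new - cost_ref
  d_effect <- effect_new - effect_ref
  if (d_effect == 0) {
    quadrant <- "undefined"
    value <- NA_real_
  } else if (d_effect > 0 && d_cost >= 0) {
    quadrant <- "more costly, more effective"
    value <- d_cost / d_effect
  } else if (d_effect > 0) {
    quadrant <- "dominant"
    value <- d_cost / d_effect
  } else if (d_cost >= 0) {
    quadrant <- "dominated"
    value <- d_cost / d_effect
  } else {
    quadrant <- "less costly, less effective"
    value <- d_cost / d_effect
  }
  structure(list(value = value, quadrant = quadrant,
                 d_cost = d_cost, d_effect = d_effect),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result>", x$quadrant, "\n")
  cat(sprintf("  d_cost %.2f / d_effect %.4f = %s per effect unit\n",
              x$d_cost, x$d_effect,
              if (is.na(x$value)) "undefined" else sprintf("%.0f", x$value)))
  invisible(x)
}
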