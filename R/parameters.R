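#' Model parameters for the five-state transition model
#'
#' Bundles the natural-history and treatment-effect parameters of the
#' model. The five transition probabilities are *annual* probabilities
#' (converted internally to the cycle length with [annual_to_cycle()]);
#' the hazard ratio is the trastuzumab effect on the two transitions into
#' distant recurrence, applied on the rate scale for the first
#' `effect_duration` years. No new recurrences (remission to local or
#' distant recurrence) occur after `recurrence_cutoff` years of follow-up.
#'
#' Defaults are the base case of the source cost-effectiveness model:
#' HERA-trial transition probabilities and hazard ratio, entry age 45,
#' monthly cycles, 5-year treatment effect, 20-year recurrence cutoff.
#'
#' @param p_R_LR Annual probability, remission to local recurrence (0.029).
#' @param p_R_DR Annual probability, remission to distant recurrence (0.087).
#' @param p_LR_R Annual probability, local recurrence back to remission (0.1).
#' @param p_LR_DR Annual probability, local to distant recurrence (0.261).
#' @param p_DR_BCD Annual probability, distant recurrence to breast-cancer
#'   death (0.325); identical in both arms.
#' @param hazard_ratio Trastuzumab hazard ratio on transitions into distant
#'   recurrence (0.59).
#' @param effect_duration Years the hazard ratio applies from model entry (5).
#' @param recurrence_cutoff Years after which no new recurrences occur (20).
#' @param start_age Age at model entry, years (45).
#' @param cycles_per_year Model cycles per year (12: monthly cycles).
#' @param max_age Age cap terminating the trace (110).
#' @param epsilon Living-occupancy threshold terminating the trace (1e-8).
#' @param half_cycle_correction Apply a half-cycle correction when accruing
#'   outcomes (default `FALSE`).
#'
#' @return An object of class `model_params` (a validated named list).
#' @export
model_params <- function(p_R_LR = 0.029,
                         p_R_DR = 0.087,
                         p_LR_R = 0.1,
                         p_LR_DR = 0.261,
                         p_DR_BCD = 0.325,
                         hazard_ratio = 0.59,
                         effect_duration = 5,
                         recurrence_cutoff = 20,
                         start_age = 45,
                         cycles_per_year = 12,
                         max_age = 110,
                         epsilon = 1e-8,
                         half_cycle_correction = FALSE) {
  p <- list(p_R_LR = p_R_LR, p_R_DR = p_R_DR, p_LR_R = p_LR_R,
            p_LR_DR = p_LR_DR, p_DR_BCD = p_DR_BCD,
            hazard_ratio = hazard_ratio, effect_duration = effect_duration,
            recurrence_cutoff = recurrence_cutoff, start_age = start_age,
            cycles_per_year = cycles_per_year, max_age = max_age,
            epsilon = epsilon, half_cycle_correction = half_cycle_correction)
  probs <- c("p_R_LR", "p_R_DR", "p_LR_R", "p_LR_DR", "p_DR_BCD")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (p$hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (p$effect_duration > p$recurrence_cutoff) {
    stop("effect_duration must not exceed recurrence_cutoff", call. = FALSE)
  }
  if (p$start_age < 0 || p$start_age >= p$max_age) {
    stop("start_age must lie in [0, max_age)", call. = FALSE)
  }
  if (p$cycles_per_year < 1) stop("cycles_per_year must be >= 1", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  annual transition probabilities: R>LR %.3f  R>DR %.3f  LR>R %.3f  LR>DR %.3f  DR>BCD %.3f\n",
              x$p_R_LR, x$p_R_DR, x$p_LR_R, x$p_LR_DR, x$p_DR_BCD))
  cat(sprintf("  hazard ratio %.3f for first %g years; recurrence cutoff %g years\n",
              x$hazard_ratio, x$effect_duration, x$recurrence_cutoff))
  cat(sprintf("  entry age %g, %d cycles/year, age cap %g\n",
              x$start_age, as.integer(x$cycles_per_year), x$max_age))
  invisible(x)
}

#' Health-state utility weights
#'
#' Utility weights in `[0, 1]` for time spent in each living state; the
#' dead states carry utility 0. Defaults are the base-case values:
#' remission 0.94, local recurrence 0.82, distant recurrence 0.58.
#'
#' @param u_R,u_LR,u_DR Utility weights for remission, local recurrence,
#'   distant recurrence.
#' @return An object of class `utilities`.
#' @export
utilities <- function(u_R = 0.94, u_LR = 0.82, u_DR = 0.58) {
  for (v in c(u_R, u_LR, u_DR)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("utilities must be single numbers in [0, 1]", call. = FALSE)
    }
  }
  structure(list(u_R = u_R, u_LR = u_LR, u_DR = u_DR, u_dead = 0),
            class = "utilities")
}

#' Cost inputs for one country
#'
#' The trastuzumab course cost and the health-state management costs.
#' `cost_LR` and `cost_DR` are *annual* costs of being managed in local /
#' distant recurrence; under the default `per_cycle` accrual they are
#' charged pro rata per cycle spent in the state (cost divided by cycles
#' per year). Under `per_episode` accrual the full amount is charged once
#' on each entry into the state. Remission carries no cost.
#'
#' @param trastuzumab_course_cost Full course cost, USD (default 20,000).
#' @param cost_R Annual cost of the remission state, USD (0).
#' @param cost_LR Annual cost of the local-recurrence state, USD.
#' @param cost_DR Annual cost of the distant-recurrence state, USD.
#' @param accrual_mode `"per_cycle"` (pro-rata per cycle in state, default)
#'   or `"per_episode"` (charged once per entry into the state).
#' @param treatment_cost_mode `"spread"` (course cost spread uniformly over
#'   the first 12 monthly cycles, discounted; default) or `"upfront"`
#'   (lump sum at cycle 0).
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(trastuzumab_course_cost = 20000,
                        cost_R = 0, cost_LR = 0, cost_DR = 0,
                        accrual_mode = c("per_cycle", "per_episode"),
                        treatment_cost_mode = c("spread", "upfront")) {
  accrual_mode <- match.arg(accrual_mode)
  treatment_cost_mode <- match.arg(treatment_cost_mode)
  for (v in c(trastuzumab_course_cost, cost_R, cost_LR, cost_DR)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("costs must be single non-negative numbers", call. = FALSE)
    }
  }
  structure(list(trastuzumab_course_cost = trastuzumab_course_cost,
                 cost_R = cost_R, cost_LR = cost_LR, cost_DR = cost_DR,
                 accrual_mode = accrual_mode,
                 treatment_cost_mode = treatment_cost_mode),
            class = "cost_inputs")
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion `p_cycle = 1 - (1 - p_annual)^(1/k)` for `k`
#' cycles per year. `p_annual = 1` maps to 1 for any `k`.
#'
#' @param p_annual Annual probability in `[0, 1]`; vectorised.
#' @param cycles_per_year Cycles per year.
#' @return Per-cycle probability.
#' @export
#' @examples
#' annual_to_cycle(0.087, 12)
annual_to_cycle <- function(p_annual, cycles_per_year = 12) {
  if (any(p_annual < 0 | p_annual > 1, na.rm = FALSE)) {
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Hazard ratios act on hazards, not probabilities: with cycle rate
#' `r = -log(1 - p)`, the modified probability is
#' `p' = 1 - exp(-hr * r) = 1 - (1 - p)^hr`.
#'
#' @param p Per-cycle probability in `[0, 1)`; vectorised.
#' @param hr Hazard ratio, positive.
#' @return Modified per-cycle probability.
#' @export
#' @examples
#' apply_hazard_ratio(annual_to_cycle(0.087), hr = 0.59)
apply_hazard_ratio <- function(p, hr) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  if (any(hr <= 0)) stop("hr must be > 0", call. = FALSE)
  1 - (1 - p)^hr
}
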