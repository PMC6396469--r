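#' trastcea: a five-state monthly-cycle state-transition model of adjuvant
#' trastuzumab for early HER2-positive breast cancer.
#'
#' @keywords internal
"_PACKAGE"

# State order used everywhere: R (remission), LR (local recurrence),
# DR (distant recurrence), BCD (breast-cancer death), D (other-cause death).
STATES <- c("R", "LR", "DR", "BCD", "D")

#' The five model states
#'
#' Returns the state labels in their canonical order: remission (`R`),
#' local recurrence (`LR`), distant recurrence (`DR`), breast-cancer death
#' (`BCD`) and other-cause death (`D`). `BCD` and `D` are absorbing.
#'
#' @return Character vector of length 5.
#' @export
model_states <- function() STATES

# Monthly (per-cycle) disease transition probabilities from the annual
# inputs. HR on the rate scale applies to the two transitions into DR.
cycle_probs <- function(params, arm, cycle_index) {
  cpy <- params$cycles_per_year
  q <- c(R_LR = annual_to_cycle(params$p_R_LR, cpy),
         R_DR = annual_to_cycle(params$p_R_DR, cpy),
         LR_R = annual_to_cycle(params$p_LR_R, cpy),
         LR_DR = annual_to_cycle(params$p_LR_DR, cpy),
         DR_BCD = annual_to_cycle(params$p_DR_BCD, cpy))
  if (arm == "trastuzumab" && cycle_index < params$effect_duration * cpy) {
    q[["R_DR"]] <- apply_hazard_ratio(q[["R_DR"]], params$hazard_ratio)
    q[["LR_DR"]] <- apply_hazard_ratio(q[["LR_DR"]], params$hazard_ratio)
  }
  if (cycle_index >= params$recurrence_cutoff * cpy) {
    # no new recurrences after the cutoff; established disease still evolves
    q[["R_LR"]] <- 0
    q[["R_DR"]] <- 0
  }
  q
}

#' Build the per-cycle transition matrix for one arm
#'
#' Assembles the 5x5 row-stochastic transition matrix at a given cycle.
#' Within a cycle, other-cause death (from the life table, converted with
#' [monthly_death_prob()]) is applied first; the disease transition
#' probabilities then act on the surviving mass, so for a living state `s`
#' the probability of moving to disease state `j` is
#' `(1 - p_death) * q_sj`. The hazard ratio modifies only the remission
#' and local-recurrence transitions into distant recurrence, only in the
#' trastuzumab arm, and only while the cycle falls inside the treatment
#' effect window; `DR -> BCD` is identical across arms. After the
#' recurrence cutoff no mass leaves remission for a recurrent state.
#'
#' @param params A [model_params()].
#' @param lt A [life_table()] covering the cohort's current age.
#' @param cycle_index Zero-based cycle counter; age is
#'   `start_age + cycle_index / cycles_per_year`.
#' @param arm `"trastuzumab"` or `"control"`.
#' @return A 5x5 matrix with `dimnames` [model_states()]; rows sum to 1.
#' @export
#' @examples
#' lt <- synth_life_table(a = 0.001, b = 0.09)
#' M <- build_transition_matrix(model_params(), lt, cycle_index = 0,
#'                              arm = "trastuzumab")
#' rowSums(M)
build_transition_matrix <- function(params, lt, cycle_index,
                                    arm = c("trastuzumab", "control")) {
  arm <- match.arg(arm)
  age <- params$start_age + cycle_index / params$cycles_per_year
  pm <- monthly_death_prob(lt, age, params$cycles_per_year)
  q <- cycle_probs(params, arm, cycle_index)
  transition_matrix_at(pm, q)
}

# pm: per-cycle other-cause death probability; q: named per-cycle disease
# transition probabilities. Death is taken first; survivors move by q.
transition_matrix_at <- function(pm, q) {
  if (q[["R_LR"]] + q[["R_DR"]] > 1 || q[["LR_R"]] + q[["LR_DR"]] > 1) {
    stop("per-cycle exit probabilities exceed 1; shorten the cycle length",
         call. = FALSE)
  }
  s <- 1 - pm
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  M["R", "LR"] <- s * q[["R_LR"]]
  M["R", "DR"] <- s * q[["R_DR"]]
  M["R", "D"] <- pm
  M["R", "R"] <- s * (1 - q[["R_LR"]] - q[["R_DR"]])
  M["LR", "R"] <- s * q[["LR_R"]]
  M["LR", "DR"] <- s * q[["LR_DR"]]
  M["LR", "D"] <- pm
  M["LR", "LR"] <- s * (1 - q[["LR_R"]] - q[["LR_DR"]])
  M["DR", "BCD"] <- s * q[["DR_BCD"]]
  M["DR", "D"] <- pm
  M["DR", "DR"] <- s * (1 - q[["DR_BCD"]])
  M["BCD", "BCD"] <- 1
  M["D", "D"] <- 1
  M
}

#' Run the model as a deterministic cohort trace
#'
#' Propagates the full cohort from `(1, 0, 0, 0, 0)` (everyone in
#' remission) by repeated application of the per-cycle transition matrix,
#' until either the living occupancy falls below `params$epsilon` or the
#' age cap is reached. The trace records state occupancy at the start of
#' each cycle, plus the per-cycle inflow into the two recurrent states
#' (needed for per-episode costing).
#'
#' @param params A [model_params()].
#' @param lt A [life_table()].
#' @param arm `"trastuzumab"` or `"control"`.
#' @return An object of class `cohort_trace`: a numeric matrix with one
#'   row per cycle (0 to T) and columns [model_states()], with attributes
#'   `arm`, `start_age`, `cycles_per_year`, and `entries` (a T x 2 matrix
#'   of new entries into LR and DR during each cycle).
#' @export
run_cohort <- function(params, lt, arm = c("trastuzumab", "control")) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "model_params"), inherits(lt, "life_table"))
  cpy <- params$cycles_per_year
  t_max <- ceiling((params$max_age - params$start_age) * cpy)
  trace <- matrix(0, t_max + 1L, 5L, dimnames = list(NULL, STATES))
  entries <- matrix(0, t_max, 2L, dimnames = list(NULL, c("LR", "DR")))
  trace[1L, ] <- c(1, 0, 0, 0, 0)
  x <- trace[1L, ]
  ages <- params$start_age + (0:(t_max - 1L)) / cpy
  pm_all <- monthly_death_prob(lt, ages, cpy)
  t_end <- t_max
  for (t in seq_len(t_max)) {
    q <- cycle_probs(params, arm, t - 1L)
    M <- transition_matrix_at(pm_all[t], q)
    entries[t, "LR"] <- x[["R"]] * M["R", "LR"]
    entries[t, "DR"] <- x[["R"]] * M["R", "DR"] + x[["LR"]] * M["LR", "DR"]
    x <- drop(x %*% M)
    trace[t + 1L, ] <- x
    if (sum(x[1:3]) < params$epsilon) {
      t_end <- t
      break
    }
  }
  residual <- sum(trace[t_end + 1L, 1:3])
  # residual living mass at the age cap is truncated; it is immaterial for
  # accrual unless appreciable, in which case the truncation is flagged
  if (t_end == t_max && residual >= 1e-4) {
    warning("cohort trace truncated at the age cap with living occupancy ",
            format(residual), call. = FALSE)
  }
  trace <- trace[seq_len(t_end + 1L), , drop = FALSE]
  structure(trace,
            arm = arm, start_age = params$start_age, cycles_per_year = cpy,
            residual_living = residual,
            entries = entries[seq_len(t_end), , drop = FALSE],
            half_cycle_correction = params$half_cycle_correction,
            class = c("cohort_trace", class(trace)))
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x) - 1L
  cpy <- attr(x, "cycles_per_year")
  cat("<cohort_trace> arm =", attr(x, "arm"), "|", n, "cycles (",
      round(n / cpy, 1), "years from age", attr(x, "start_age"), ")\n")
  last <- x[nrow(x), ]
  cat(sprintf("  final occupancy: R %.2e LR %.2e DR %.2e BCD %.4f D %.4f\n",
              last[1], last[2], last[3], last[4], last[5]))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' Writes columns `cycle,age,R,LR,DR,BCD,D` at full precision.
#'
#' @param trace A [run_cohort()] trace.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  cyc <- seq_len(nrow(trace)) - 1L
  df <- data.frame(cycle = cyc,
                   age = attr(trace, "start_age") +
                     cyc / attr(trace, "cycles_per_year"))
  df <- cbind(df, as.data.frame(unclass(trace)[, , drop = FALSE]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the model as an individual-level microsimulation
#'
#' Samples `n_patients` independent patient paths cycle-by-cycle from the
#' same transition matrices as [run_cohort()], so the cohort trace is the
#' exact expectation of the microsimulation. Next states are drawn by
#' inverting the cumulative transition probabilities in the fixed state
#' order R, LR, DR, BCD, D. Discounted life years, QALYs and costs are
#' accrued per patient, yielding means and standard errors; the full state
#' paths can be kept for inspection.
#'
#' @param params A [model_params()].
#' @param lt A [life_table()].
#' @param arm `"trastuzumab"` or `"control"`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; identical seeds give identical output.
#' @param costs A [cost_inputs()]; used for per-patient cost accrual. The
#'   trastuzumab course cost is added (as its discounted schedule value)
#'   to every patient in the trastuzumab arm.
#' @param utils_ A [utilities()].
#' @param annual_rate Annual discount rate (default 0.03).
#' @param keep_paths Keep the full patient-by-cycle state matrix
#'   (integer codes into [model_states()]); default `FALSE`.
#' @return An object of class `microsim_result`: a list with `summary`
#'   (a data frame of mean and standard error for LY, QALY and cost),
#'   per-patient vectors `ly`, `qaly`, `cost`, the arm, `n_patients`, and
#'   optionally `paths`.
#' @export
run_microsim <- function(params, lt, arm = c("trastuzumab", "control"),
                         n_patients = 10000, seed = 1,
                         costs = cost_inputs(), utils_ = utilities(),
                         annual_rate = 0.03, keep_paths = FALSE) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "model_params"), inherits(lt, "life_table"),
            n_patients >= 1)
  set.seed(seed)
  cpy <- params$cycles_per_year
  t_max <- ceiling((params$max_age - params$start_age) * cpy)
  ages <- params$start_age + (0:(t_max - 1L)) / cpy
  pm_all <- monthly_death_prob(lt, ages, cpy)
  df_all <- discount_factor(0:(t_max - 1L), annual_rate, cpy)

  state_cost <- c(costs$cost_R, costs$cost_LR, costs$cost_DR, 0, 0)
  state_util <- c(utils_$u_R, utils_$u_LR, utils_$u_DR, 0, 0)
  per_episode <- costs$accrual_mode == "per_episode"

  state <- rep.int(1L, n_patients)          # everyone enters in remission
  ly <- qaly <- cost <- numeric(n_patients)
  paths <- if (keep_paths) matrix(NA_integer_, n_patients, t_max + 1L)
  if (keep_paths) paths[, 1L] <- state

  for (t in seq_len(t_max)) {
    alive <- which(state < 4L)
    if (length(alive) == 0L) {
      if (keep_paths) paths[, t + 1L] <- state
      next
    }
    dft <- df_all[t]
    # accrual for the cycle being lived (state at cycle start)
    ly[alive] <- ly[alive] + dft / cpy
    qaly[alive] <- qaly[alive] + dft * state_util[state[alive]] / cpy
    if (!per_episode) {
      cost[alive] <- cost[alive] + dft * state_cost[state[alive]] / cpy
    }
    q <- cycle_probs(params, arm, t - 1L)
    M <- transition_matrix_at(pm_all[t], q)
    new_state <- state
    for (s in 1:3) {
      idx <- alive[state[alive] == s]
      if (length(idx) == 0L) next
      cum <- cumsum(M[s, ])
      cum[5L] <- 1
      new_state[idx] <- findInterval(stats::runif(length(idx)), cum) + 1L
    }
    if (per_episode) {
      df_next <- if (t < t_max) df_all[t + 1L] else df_all[t]
      ent_lr <- new_state == 2L & state != 2L
      ent_dr <- new_state == 3L & state != 3L
      cost[ent_lr] <- cost[ent_lr] + df_next * costs$cost_LR
      cost[ent_dr] <- cost[ent_dr] + df_next * costs$cost_DR
    }
    state <- new_state
    if (keep_paths) paths[, t + 1L] <- state
  }

  if (arm == "trastuzumab") {
    cost <- cost + treatment_cost_schedule(costs$trastuzumab_course_cost,
                                           annual_rate = annual_rate,
                                           mode = costs$treatment_cost_mode,
                                           cycles_per_year = cpy)
  }
  summ <- data.frame(
    quantity = c("LY", "QALY", "cost"),
    mean = c(mean(ly), mean(qaly), mean(cost)),
    se = c(stats::sd(ly), stats::sd(qaly), stats::sd(cost)) / sqrt(n_patients)
  )
  out <- list(summary = summ, ly = ly, qaly = qaly, cost = cost,
              arm = arm, n_patients = n_patients, seed = seed)
  if (keep_paths) out$paths <- paths
  structure(out, class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> arm =", x$arm, "| n =", x$n_patients, "\n")
  s <- x$summary
  cat(sprintf("  %-5s mean %10.4f  se %.4f\n", s$quantity, s$mean, s$se),
      sep = "")
  invisible(x)
}
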