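#' Full cost-effectiveness comparison of the two arms
#'
#' Runs the model for the trastuzumab and control arms — deterministically
#' ([run_cohort()]) or as a microsimulation ([run_microsim()]) — accrues
#' discounted life years, QALYs and costs, and forms the increments and
#' both ICER variants (per QALY and per LY).
#'
#' @param params A [model_params()].
#' @param lt A [life_table()].
#' @param costs A [cost_inputs()].
#' @param utils_ A [utilities()].
#' @param annual_rate Annual discount rate (default 0.03).
#' @param mode `"cohort"` (default) or `"microsim"`.
#' @param n_patients,seed Microsimulation size and seed (microsim mode).
#' @param label Optional label (e.g. the country) carried in the result.
#' @return An object of class `cea_result`: a list with `arms` (data frame
#'   of discounted LY/QALY/cost per arm, plus standard errors in microsim
#'   mode), `d_ly`, `d_qaly`, `d_cost`, `icer_qaly`, `icer_ly` (each an
#'   [icer()] result), `mode` and `label`.
#' @export
#' @examples
#' sc <- reference_scenario("Congo")
#' run_cea(model_params(), sc$life_table, sc$costs, label = sc$country)
run_cea <- function(params = model_params(), lt, costs = cost_inputs(),
                    utils_ = utilities(), annual_rate = 0.03,
                    mode = c("cohort", "microsim"),
                    n_patients = 10000, seed = 1, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "cohort") {
    res <- lapply(c("trastuzumab", "control"), function(arm) {
      accrue(run_cohort(params, lt, arm), costs, utils_, annual_rate)
    })
    arms <- data.frame(arm = c("trastuzumab", "control"),
                       ly = vapply(res, `[[`, 0, "ly"),
                       qaly = vapply(res, `[[`, 0, "qaly"),
                       cost = vapply(res, `[[`, 0, "cost"))
  } else {
    sims <- lapply(seq_along(c("trastuzumab", "control")), function(i) {
      arm <- c("trastuzumab", "control")[i]
      # distinct substreams so the two arms are independent draws
      run_microsim(params, lt, arm, n_patients = n_patients,
                   seed = seed_substream(seed, arm),
                   costs = costs, utils_ = utils_, annual_rate = annual_rate)
    })
    arms <- do.call(rbind, lapply(sims, function(s) {
      m <- s$summary
      data.frame(arm = s$arm,
                 ly = m$mean[1], qaly = m$mean[2], cost = m$mean[3],
                 se_ly = m$se[1], se_qaly = m$se[2], se_cost = m$se[3])
    }))
  }
  tz <- arms[arms$arm == "trastuzumab", ]
  ct <- arms[arms$arm == "control", ]
  out <- list(arms = arms,
              d_ly = tz$ly - ct$ly,
              d_qaly = tz$qaly - ct$qaly,
              d_cost = tz$cost - ct$cost,
              icer_qaly = icer(tz$cost, tz$qaly, ct$cost, ct$qaly),
              icer_ly = icer(tz$cost, tz$ly, ct$cost, ct$ly),
              mode = mode, label = label, annual_rate = annual_rate)
  structure(out, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>", if (!is.null(x$label)) x$label else "", "(", x$mode,
      "mode )\n")
  a <- x$arms
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-12s LY %6.2f  QALY %6.2f  cost %10.0f USD\n",
                a$arm[i], a$ly[i], a$qaly[i], a$cost[i]))
  }
  cat(sprintf("  increments   LY %6.2f  QALY %6.2f  cost %10.0f USD\n",
              x$d_ly, x$d_qaly, x$d_cost))
  cat(sprintf("  ICER %s USD/QALY | %s USD/LY\n",
              fmt_icer(x$icer_qaly), fmt_icer(x$icer_ly)))
  invisible(x)
}

fmt_icer <- function(ic) {
  if (is.na(ic$value)) ic$quadrant else sprintf("%.0f (%s)", ic$value,
                                                ic$quadrant)
}

#' Tabulate one or more CEA results
#'
#' Flattens [run_cea()] results into one data frame with a row per
#' (label, arm) and an increments row, columns
#' `label,arm,LY,QALY,cost,dLY,dQALY,dcost,icer_qaly,icer_ly`.
#'
#' @param results A `cea_result` or a list of them.
#' @return A data frame.
#' @export
cea_table <- function(results) {
  if (inherits(results, "cea_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    lab <- if (is.null(r$label)) "" else r$label
    a <- r$arms
    rows <- data.frame(label = lab, arm = a$arm,
                       LY = a$ly, QALY = a$qaly, cost = a$cost,
                       dLY = NA_real_, dQALY = NA_real_, dcost = NA_real_,
                       icer_qaly = NA_real_, icer_ly = NA_real_)
    inc <- data.frame(label = lab, arm = "increment",
                      LY = NA_real_, QALY = NA_real_, cost = NA_real_,
                      dLY = r$d_ly, dQALY = r$d_qaly, dcost = r$d_cost,
                      icer_qaly = r$icer_qaly$value, icer_ly = r$icer_ly$value)
    rbind(rows, inc)
  }))
}

#' Write CEA results to CSV
#'
#' Writes the [cea_table()] at full precision (rounding is left to
#' human-readable summaries).
#'
#' @param results A `cea_result` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cea_results <- function(results, path) {
  utils::write.csv(cea_table(results), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deterministic substream seeds below 2^31, from a master seed and a label.
seed_substream <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 1009001
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}
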