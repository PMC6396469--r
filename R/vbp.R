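#' Solve for the value-based trastuzumab price
#'
#' Finds the course price at which the incremental cost-effectiveness
#' ratio equals a willingness-to-pay threshold (typically 1x or 3x GDP
#' per capita per WHO guidance). The state-transition process does not
#' depend on the drug price, so the incremental discounted cost is affine
#' in the course price: `d_cost(price) = a * price + b`, where `a` is the
#' discounted value of one price unit under the treatment-cost schedule
#' and `b` is the (price-independent) difference in state costs. The
#' exact solution is `price = (wtp * d_qaly - b) / a`, clipped at zero
#' (and flagged) when the threshold is unattainable even for a free drug.
#' A bisection fallback that re-evaluates the full accrual verifies the
#' closed form.
#'
#' @param params,lt,costs,utils_,annual_rate Model inputs as in
#'   [run_cea()]; `costs` supplies everything except the solved price.
#' @param wtp Willingness-to-pay threshold, USD per QALY; positive.
#' @param wtp_multiple Optional annotation (1 or 3) carried in the result.
#' @param label Optional country label.
#' @param check Also run the bisection fallback and assert agreement to
#'   `tol` relative (default `TRUE`).
#' @param tol Relative agreement required between closed form and
#'   bisection (default 1e-6).
#' @return An object of class `vbp_result`: list with `solved_price`,
#'   `achieved_icer`, `wtp`, `wtp_multiple`, `clipped`, `d_qaly`, `label`.
#' @export
#' @examples
#' sc <- reference_scenario("Congo")
#' solve_vbp(model_params(), sc$life_table, sc$costs,
#'           wtp = sc$gdp_per_capita, label = sc$country)
solve_vbp <- function(params = model_params(), lt, costs = cost_inputs(),
                      utils_ = utilities(), annual_rate = 0.03,
                      wtp, wtp_multiple = NA, label = NULL,
                      check = TRUE, tol = 1e-6) {
  if (!is.numeric(wtp) || length(wtp) != 1L || wtp <= 0) {
    stop("wtp must be a single positive number", call. = FALSE)
  }
  traces <- list(tz = run_cohort(params, lt, "trastuzumab"),
                 ct = run_cohort(params, lt, "control"))
  cost_at <- function(price) {
    cs <- cost_inputs(price, costs$cost_R, costs$cost_LR, costs$cost_DR,
                      costs$accrual_mode, costs$treatment_cost_mode)
    tz <- accrue(traces$tz, cs, utils_, annual_rate)
    ct <- accrue(traces$ct, cs, utils_, annual_rate)
    list(d_cost = tz$cost - ct$cost, d_qaly = tz$qaly - ct$qaly)
  }
  at0 <- cost_at(0)
  d_qaly <- at0$d_qaly
  if (d_qaly <= 0) {
    stop(structure(class = c("vbp_undefined_error", "error", "condition"),
                   list(message = paste0("no finite value-based price: ",
                                         "incremental QALYs are not positive"),
                        call = NULL)))
  }
  b <- at0$d_cost                                     # zero-price intercept
  a <- treatment_cost_schedule(1, annual_rate,
                               mode = costs$treatment_cost_mode,
                               cycles_per_year = params$cycles_per_year)
  price <- (wtp * d_qaly - b) / a
  clipped <- price < 0
  if (clipped) price <- 0
  if (check && !clipped) {
    f <- function(p) cost_at(p)$d_cost / d_qaly - wtp
    hi <- max(price * 2, 1)
    while (f(hi) < 0) hi <- hi * 2
    root <- stats::uniroot(f, c(0, hi), tol = max(price, 1) * tol / 10)$root
    if (abs(root - price) > tol * max(price, 1)) {
      stop("closed-form and bisection value-based prices disagree",
           call. = FALSE)
    }
  }
  achieved <- (a * price + b) / d_qaly
  structure(list(solved_price = price, achieved_icer = achieved,
                 wtp = wtp, wtp_multiple = wtp_multiple, clipped = clipped,
                 d_qaly = d_qaly, label = label),
            class = "vbp_result")
}

#' @export
print.vbp_result <- function(x, ...) {
  cat("<vbp_result>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  WTP %.0f USD/QALY%s -> course price %.0f USD (ICER %.0f)%s\n",
              x$wtp,
              if (is.na(x$wtp_multiple)) "" else
                sprintf(" (%gx GDP per capita)", x$wtp_multiple),
              x$solved_price, x$achieved_icer,
              if (x$clipped) " [clipped at 0: unattainable]" else ""))
  invisible(x)
}

#' Value-based prices for a set of country scenarios
#'
#' Solves [solve_vbp()] at `multiple` times each country's GDP per capita
#' and tabulates `country,gdp_per_capita,wtp,solved_price,achieved_icer`,
#' echoing the user-supplied GDP value for auditability.
#'
#' @param scenarios List of [reference_scenario()] /
#'   [random_scenario()] objects.
#' @param params,utils_,annual_rate Shared model inputs.
#' @param multiple WTP multiple of GDP per capita (1 or 3; default 1).
#' @return A data frame, one row per country.
#' @export
vbp_table <- function(scenarios, params = model_params(),
                      utils_ = utilities(), annual_rate = 0.03,
                      multiple = 1) {
  if (inherits(scenarios, "country_scenario")) scenarios <- list(scenarios)
  do.call(rbind, lapply(scenarios, function(sc) {
    v <- solve_vbp(params, sc$life_table, sc$costs, utils_, annual_rate,
                   wtp = multiple * sc$gdp_per_capita,
                   wtp_multiple = multiple, label = sc$country,
                   check = FALSE)
    data.frame(country = sc$country, gdp_per_capita = sc$gdp_per_capita,
               wtp = v$wtp, solved_price = v$solved_price,
               achieved_icer = v$achieved_icer, clipped = v$clipped)
  }))
}
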