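# Base-case cost inputs per country (USD): full trastuzumab course, annual
# local-recurrence and distant-recurrence management costs. Recurrence
# costs were derived by the source analysis from Bolivian prices scaled by
# GDP per capita, hence the constant DR/LR ratio across countries.
REFERENCE_COSTS <- data.frame(
  country = c("Congo", "Ethiopia", "Guinea", "Kenya", "Namibia", "Nigeria",
              "Rwanda", "Uganda", "Zambia", "Zimbabwe", "South Africa"),
  trastuzumab = 20000,
  cost_LR = c(974, 1323, 1136, 2769, 9719, 5446, 1456, 1424, 2695, 2090,
              11836),
  cost_DR = c(1356, 1841, 1581, 3853, 13524, 7578, 2027, 1981, 3751, 2909,
              16470)
)

# Calibration targets for the surrogate life tables: approximate female
# life expectancy at age 45 (years), World Bank / WHO estimates around
# 2016, rounded to the nearest year. These stand in for the per-country
# WHO abridged life tables when no real table is supplied.
SURROGATE_E45 <- c(Congo = 29, Ethiopia = 31, Guinea = 28, Kenya = 31,
                   Namibia = 30, Nigeria = 26, Rwanda = 31, Uganda = 29,
                   Zambia = 29, Zimbabwe = 28, `South Africa` = 29)

# Approximate World Bank GDP per capita (current USD, ~2015-2016). These
# are illustrative defaults for the value-based-price examples; analyses
# should supply their own vintage.
REFERENCE_GDP <- c(Congo = 475, Ethiopia = 720, Guinea = 660, Kenya = 1455,
                   Namibia = 5050, Nigeria = 2450, Rwanda = 715,
                   Uganda = 660, Zambia = 1270, Zimbabwe = 1030,
                   `South Africa` = 5750)

#' Countries with built-in reference inputs
#'
#' @return Character vector of the 11 studied countries.
#' @export
reference_countries <- function() REFERENCE_COSTS$country

#' Remaining life expectancy implied by a Gompertz hazard
#'
#' Expected further years of life at `age0` under the continuous hazard
#' `h(t) = a * exp(b * t)`, integrated up to `max_age`.
#'
#' @param a,b Gompertz level and slope (per year).
#' @param age0 Starting age (years).
#' @param max_age Upper integration limit.
#' @return Expected remaining years.
#' @export
gompertz_life_expectancy <- function(a, b, age0 = 45, max_age = 110) {
  surv <- function(t) {
    if (b == 0) exp(-a * t) else
      exp(-(a / b) * exp(b * age0) * (exp(b * t) - 1))
  }
  stats::integrate(Vectorize(surv), 0, max_age - age0, rel.tol = 1e-10)$value
}

# Solve the Gompertz level a so remaining life expectancy at age0 hits a
# target, for fixed slope b.
gompertz_a_for_e <- function(e_target, b = 0.09, age0 = 45, max_age = 110) {
  f <- function(log_a) {
    gompertz_life_expectancy(exp(log_a), b, age0, max_age) - e_target
  }
  exp(stats::uniroot(f, c(log(1e-8), log(0.05)), tol = 1e-12)$root)
}

#' Surrogate background-mortality life table for a studied country
#'
#' A synthetic stand-in for the country's WHO abridged life table:
#' a Gompertz law with slope 0.09/yr whose level is solved so that
#' remaining life expectancy at age 45 matches an approximate national
#' value (see the package vignette). Use [read_life_table()] with a real
#' WHO table whenever one is available; this surrogate is never
#' substituted silently — it is only produced by calling this function.
#'
#' @param country One of [reference_countries()].
#' @param b Gompertz slope (default 0.09/yr).
#' @return A [life_table()] labelled `"<country> (surrogate)"`.
#' @export
surrogate_life_table <- function(country, b = 0.09) {
  if (!country %in% names(SURROGATE_E45)) {
    stop_unknown_country(country)
  }
  a <- gompertz_a_for_e(SURROGATE_E45[[country]], b = b)
  synth_life_table(a, b, max_age = 110,
                   country = paste0(country, " (surrogate)"))
}

stop_unknown_country <- function(country) {
  stop(structure(class = c("unknown_country_error", "error", "condition"),
                 list(message = paste0("unknown country: '", country,
                                       "'; see reference_countries()"),
                      call = NULL)))
}

#' Reference scenario for one of the studied countries
#'
#' Bundles the country's published cost inputs with a background-mortality
#' life table and a GDP-per-capita value into a ready-to-run scenario.
#' The cost figures are the published per-country values; the life table
#' defaults to the [surrogate_life_table()] (pass a real WHO table via
#' `life_table` to override), and the GDP value is an approximate default
#' that callers should replace with their preferred vintage.
#'
#' @param country One of [reference_countries()].
#' @param life_table Optional [life_table()] replacing the surrogate.
#' @param gdp_per_capita Optional GDP per capita (USD) replacing the
#'   built-in approximation.
#' @param accrual_mode,treatment_cost_mode Passed to [cost_inputs()].
#' @return An object of class `country_scenario`: list with `country`,
#'   `life_table`, `costs`, `gdp_per_capita`, `life_table_source`.
#' @export
#' @examples
#' sc <- reference_scenario("South Africa")
#' sc$costs$cost_DR   # 16,470 USD/year
reference_scenario <- function(country, life_table = NULL,
                               gdp_per_capita = NULL,
                               accrual_mode = "per_cycle",
                               treatment_cost_mode = "spread") {
  row <- REFERENCE_COSTS[REFERENCE_COSTS$country == country, ]
  if (nrow(row) != 1L) stop_unknown_country(country)
  lt_source <- if (is.null(life_table)) "surrogate" else "user-supplied"
  if (is.null(life_table)) life_table <- surrogate_life_table(country)
  stopifnot(inherits(life_table, "life_table"))
  if (is.null(gdp_per_capita)) gdp_per_capita <- REFERENCE_GDP[[country]]
  structure(list(country = country,
                 life_table = life_table,
                 costs = cost_inputs(row$trastuzumab, 0, row$cost_LR,
                                     row$cost_DR, accrual_mode,
                                     treatment_cost_mode),
                 gdp_per_capita = gdp_per_capita,
                 life_table_source = lt_source),
            class = "country_scenario")
}

#' Generate a random, self-consistent country scenario
#'
#' Draws a complete scenario for property-style testing: a Gompertz life
#' table whose slope and adult life expectancy are drawn from ranges
#' typical of sub-Saharan settings, recurrence costs log-uniform across
#' the span of the published country costs (with the distant-recurrence
#' cost constrained above the local-recurrence cost, as in every
#' published row), and a plausible GDP per capita. Fully reproducible
#' from the seed.
#'
#' @param seed Integer seed.
#' @return A `country_scenario` (see [reference_scenario()]).
#' @export
random_scenario <- function(seed = 1) {
  set.seed(seed)
  b <- stats::runif(1, 0.08, 0.105)
  e45 <- stats::runif(1, 24, 34)
  a <- gompertz_a_for_e(e45, b = b)
  lt <- synth_life_table(a, b, max_age = 110,
                         country = sprintf("random-%d", seed))
  cost_lr <- exp(stats::runif(1, log(900), log(12000)))
  cost_dr <- cost_lr * stats::runif(1, 1.2, 1.6)
  gdp <- exp(stats::runif(1, log(400), log(6000)))
  structure(list(country = sprintf("random-%d", seed),
                 life_table = lt,
                 costs = cost_inputs(20000, 0, cost_lr, cost_dr),
                 gdp_per_capita = gdp,
                 life_table_source = "synthetic"),
            class = "country_scenario")
}

#' @export
print.country_scenario <- function(x, ...) {
  cat("<country_scenario>", x$country, "\n")
  cat(sprintf("  life table: %s | GDP per capita %.0f USD\n",
              x$life_table_source, x$gdp_per_capita))
  cat(sprintf("  costs (USD): course %.0f, LR %.0f/yr, DR %.0f/yr (%s, %s)\n",
              x$costs$trastuzumab_course_cost, x$costs$cost_LR,
              x$costs$cost_DR, x$costs$accrual_mode,
              x$costs$treatment_cost_mode))
  invisible(x)
}
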