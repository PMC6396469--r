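#' Read and validate a run configuration
#'
#' Parses a YAML configuration describing one model run. Recognised keys
#' (all optional unless noted):
#' * `country` — one of [reference_countries()], *or* `life_table` — path
#'   to a life-table CSV (one of the two is required);
#' * `params` — a mapping overriding [model_params()] fields;
#' * `utilities` — overrides for `u_R`, `u_LR`, `u_DR`;
#' * `costs` — overrides for [cost_inputs()] fields, including
#'   `accrual_mode` and `treatment_cost_mode`;
#' * `discount_rate` — annual rate (default 0.03);
#' * `mode` — `"cohort"` (default) or `"microsim"`;
#' * `n_patients`, `seed` — required iff `mode: microsim`;
#' * `gdp_per_capita` — used by the value-based-price step;
#' * `output_dir` — where [run_base_case()] writes results.
#'
#' Validation problems are collected and reported together in a single
#' aggregated error, naming each offending field.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  problems <- character()
  if (is.null(raw$country) && is.null(raw$life_table)) {
    problems <- c(problems, "one of `country` or `life_table` is required")
  }
  if (!is.null(raw$country) && !raw$country %in% reference_countries()) {
    problems <- c(problems,
                  sprintf("`country`: unknown country '%s'", raw$country))
  }
  if (!is.null(raw$life_table) && !file.exists(raw$life_table)) {
    problems <- c(problems,
                  sprintf("`life_table`: file not found '%s'", raw$life_table))
  }
  mode <- if (is.null(raw$mode)) "cohort" else raw$mode
  if (!mode %in% c("cohort", "microsim")) {
    problems <- c(problems, "`mode` must be 'cohort' or 'microsim'")
  }
  if (mode == "microsim") {
    if (is.null(raw$n_patients)) {
      problems <- c(problems, "`n_patients` is required in microsim mode")
    }
    if (is.null(raw$seed)) {
      problems <- c(problems, "`seed` is required in microsim mode")
    }
  }
  if (!is.null(raw$discount_rate) &&
      (!is.numeric(raw$discount_rate) || raw$discount_rate < 0)) {
    problems <- c(problems, "`discount_rate` must be a non-negative number")
  }
  if (length(problems) > 0L) {
    stop(structure(class = c("config_validation_error", "error", "condition"),
                   list(message = paste0("invalid run configuration:\n",
                                         paste0("  - ", problems,
                                                collapse = "\n")),
                        call = NULL)))
  }
  params <- do.call(model_params, raw$params %||% list())
  utils_ <- do.call(utilities, raw$utilities %||% list())
  cost_over <- raw$costs %||% list()
  scenario <- if (!is.null(raw$country)) {
    sc <- reference_scenario(
      raw$country,
      life_table = if (!is.null(raw$life_table))
        read_life_table(raw$life_table, raw$country),
      gdp_per_capita = raw$gdp_per_capita,
      accrual_mode = cost_over$accrual_mode %||% "per_cycle",
      treatment_cost_mode = cost_over$treatment_cost_mode %||% "spread")
    for (nm in intersect(names(cost_over),
                         c("trastuzumab_course_cost", "cost_R", "cost_LR",
                           "cost_DR"))) {
      sc$costs[[nm]] <- cost_over[[nm]]
    }
    sc
  } else {
    lt <- read_life_table(raw$life_table)
    structure(list(country = attr(lt, "country"), life_table = lt,
                   costs = do.call(cost_inputs, cost_over),
                   gdp_per_capita = raw$gdp_per_capita %||% NA_real_,
                   life_table_source = "user-supplied"),
              class = "country_scenario")
  }
  structure(list(scenario = scenario, params = params, utils_ = utils_,
                 discount_rate = raw$discount_rate %||% 0.03,
                 mode = mode, n_patients = raw$n_patients %||% 10000,
                 seed = raw$seed %||% 1,
                 output_dir = raw$output_dir %||% "."),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the base-case analysis for one configuration
#'
#' Executes [run_cea()] under a validated configuration, writes the
#' results CSV and a human-readable summary into the configured output
#' directory, and writes a run manifest recording every resolved
#' modelling switch (probability-conversion convention, cost accrual
#' mode, treatment-cost schedule, half-cycle correction, seeds) so the
#' run is auditable and reproducible.
#'
#' @param config A [read_run_config()] object (or a path to a YAML file).
#' @return The [run_cea()] result, invisibly; files are written as a side
#'   effect (`results.csv`, `summary.txt`, `manifest.yaml`).
#' @export
run_base_case <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  res <- run_cea(config$params, sc$life_table, sc$costs, config$utils_,
                 config$discount_rate, mode = config$mode,
                 n_patients = config$n_patients, seed = config$seed,
                 label = sc$country)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_cea_results(res, file.path(config$output_dir, "results.csv"))
  writeLines(c(
    sprintf("Country: %s (life table: %s)", sc$country,
            sc$life_table_source),
    sprintf("Mode: %s", config$mode),
    sprintf("Trastuzumab arm: %.2f LY, %.2f QALY, %.0f USD",
            res$arms$ly[1], res$arms$qaly[1], res$arms$cost[1]),
    sprintf("Control arm:     %.2f LY, %.2f QALY, %.0f USD",
            res$arms$ly[2], res$arms$qaly[2], res$arms$cost[2]),
    sprintf("Increments:      %.2f LY, %.2f QALY, %.0f USD",
            res$d_ly, res$d_qaly, res$d_cost),
    sprintf("ICER: %s USD/QALY | %s USD/LY",
            fmt_icer(res$icer_qaly), fmt_icer(res$icer_ly))
  ), file.path(config$output_dir, "summary.txt"))
  manifest <- list(
    country = sc$country,
    life_table_source = sc$life_table_source,
    mode = config$mode,
    n_patients = if (config$mode == "microsim") config$n_patients,
    seed = if (config$mode == "microsim") config$seed,
    discount_rate = config$discount_rate,
    probability_conversion = "annual-to-monthly, constant hazard",
    hazard_ratio_scale = "rate",
    competing_risk_order = "other-cause death first, survivors by disease",
    accrual_mode = sc$costs$accrual_mode,
    treatment_cost_mode = sc$costs$treatment_cost_mode,
    half_cycle_correction = config$params$half_cycle_correction
  )
  yaml::write_yaml(manifest[!vapply(manifest, is.null, TRUE)],
                   file.path(config$output_dir, "manifest.yaml"))
  invisible(res)
}

#' Run the base case for every scenario in a set
#'
#' Runs [run_cea()] per scenario, isolating per-country failures: a
#' scenario that errors is reported in the `failures` attribute while the
#' remaining countries still run.
#'
#' @param scenarios Non-empty list of `country_scenario` objects (e.g.
#'   from [reference_scenario()]).
#' @param params,utils_,annual_rate Shared model inputs.
#' @param mode,n_patients,seed Passed to [run_cea()].
#' @return A [cea_table()] data frame covering all successful countries,
#'   with attribute `failures` (named character vector of error messages)
#'   and attribute `results` (the underlying `cea_result` list).
#' @export
run_all_countries <- function(scenarios, params = model_params(),
                              utils_ = utilities(), annual_rate = 0.03,
                              mode = "cohort", n_patients = 10000,
                              seed = 1) {
  if (inherits(scenarios, "country_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L) {
    stop("empty scenario list", call. = FALSE)
  }
  results <- list()
  failures <- character()
  for (sc in scenarios) {
    r <- tryCatch(
      run_cea(params, sc$life_table, sc$costs, utils_, annual_rate,
              mode = mode, n_patients = n_patients, seed = seed,
              label = sc$country),
      error = function(e) e)
    if (inherits(r, "error")) {
      failures[sc$country] <- conditionMessage(r)
    } else {
      results[[sc$country]] <- r
    }
  }
  if (length(results) == 0L) {
    stop("every scenario failed:\n",
         paste0("  ", names(failures), ": ", failures, collapse = "\n"),
         call. = FALSE)
  }
  out <- cea_table(results)
  attr(out, "failures") <- failures
  attr(out, "results") <- results
  out
}
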