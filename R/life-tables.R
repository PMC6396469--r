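#' Construct a life table of five-year death probabilities
#'
#' A life table holds country background (all-cause) mortality as the
#' probability `q5` of dying between ages `x` and `x + 5`, one row per
#' five-year age band, as published in WHO Global Health Observatory
#' abridged life tables. The bands must be contiguous, non-overlapping and
#' ascending; every band except possibly the terminal one must be exactly
#' five years wide. The terminal band may be open (`age_end = Inf`), in
#' which case its `q5` must be 1 (everyone eventually dies).
#'
#' @param age_start Numeric vector of band lower bounds (years).
#' @param age_end Numeric vector of band upper bounds (years); the last
#'   entry may be `Inf`.
#' @param q5 Probability of dying within each band, in `[0, 1]`.
#' @param country Single character label for the population.
#'
#' @return An object of class `life_table`: a data frame with columns
#'   `age_start`, `age_end`, `q5` and attribute `country`.
#' @seealso [read_life_table()], [synth_life_table()], [monthly_death_prob()]
#' @export
#' @examples
#' lt <- life_table(c(0, 5, 10), c(5, 10, Inf), c(0.05, 0.01, 1), "demo")
#' monthly_death_prob(lt, age = 2)
life_table <- function(age_start, age_end, q5, country = "unnamed") {
  if (!is.character(country) || length(country) != 1L || is.na(country)) {
    stop("`country` must be a single character label", call. = FALSE)
  }
  n <- length(age_start)
  if (length(age_end) != n || length(q5) != n || n == 0L) {
    stop("`age_start`, `age_end`, `q5` must be non-empty and equal length",
         call. = FALSE)
  }
  if (!is.numeric(age_start) || !is.numeric(age_end) || !is.numeric(q5) ||
      anyNA(age_start) || anyNA(age_end) || anyNA(q5)) {
    stop_lt_nonnumeric("life table columns must be numeric and non-missing")
  }
  if (any(q5 < 0 | q5 > 1)) {
    stop_lt_range("every q5 must lie in [0, 1]")
  }
  widths <- age_end - age_start
  if (any(widths[-n] != 5) || (is.finite(age_end[n]) && widths[n] != 5)) {
    stop_lt_bands("all bands but a terminal open band must be 5 years wide")
  }
  if (n > 1L && any(age_start[-1L] != age_end[-n])) {
    stop_lt_bands("bands must be contiguous, non-overlapping and ascending")
  }
  if (!is.finite(age_end[n]) && q5[n] != 1) {
    stop_lt_range("a terminal open band must have q5 = 1")
  }
  out <- data.frame(age_start = as.numeric(age_start),
                    age_end = as.numeric(age_end),
                    q5 = as.numeric(q5))
  structure(out, country = country, class = c("life_table", "data.frame"))
}

# Distinct condition classes so callers can tell a parse failure from an
# invariant violation.
stop_lt_nonnumeric <- function(msg) {
  stop(structure(class = c("lt_nonnumeric_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
stop_lt_range <- function(msg) {
  stop(structure(class = c("lt_range_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
stop_lt_bands <- function(msg) {
  stop(structure(class = c("lt_contiguity_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ", attr(x, "country"), ": ", nrow(x),
      " age bands, ages ", x$age_start[1L], "-",
      if (is.finite(x$age_end[nrow(x)])) x$age_end[nrow(x)] else paste0(x$age_start[nrow(x)], "+"),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 25L), ...)
  if (nrow(x) > 25L) cat("... and", nrow(x) - 25L, "more bands\n")
  invisible(x)
}

#' Read a life table from CSV
#'
#' Expects a UTF-8 CSV with header `age_start,age_end,q5` and one row per
#' five-year band. The file is validated against all [life_table()]
#' invariants; offending files raise distinct error classes
#' (`lt_nonnumeric_error`, `lt_range_error`, `lt_contiguity_error`).
#'
#' @param path Path to the CSV file.
#' @param country Label for the population; defaults to the file name.
#' @return A validated [life_table()].
#' @export
read_life_table <- function(path, country = NULL) {
  if (!file.exists(path)) {
    stop("life-table file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "age_end", "q5")
  if (!all(need %in% names(df))) {
    stop("life-table CSV must have columns age_start,age_end,q5", call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      stop_lt_nonnumeric(sprintf("column '%s' is not numeric", col))
    }
  }
  if (is.null(country)) country <- sub("\\.csv$", "", basename(path))
  life_table(df$age_start, df$age_end, df$q5, country = country)
}

#' Write a life table to CSV
#'
#' Inverse of [read_life_table()]: writes `age_start,age_end,q5` so a
#' read-back reproduces the table exactly.
#'
#' @param lt A [life_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-cycle probability of other-cause death at a given age
#'
#' Converts the five-year band probability covering `age` into a monthly
#' probability under the standard actuarial assumption of constant hazard
#' within the band: `p_month = 1 - (1 - q5)^(1/60)`. The result is
#' piecewise constant in age; band lookup uses half-open intervals
#' `[age_start, age_end)`. Ages beyond the last band are clamped to the
#' terminal band so hazards never vanish in old age. A terminal band with
#' `q5 = 1` is absorbing: the monthly probability is 1.
#'
#' @param lt A [life_table()].
#' @param age Age in (decimal) years; vectorised.
#' @param cycles_per_year Cycles per year, default 12 (monthly).
#' @return Per-cycle death probability, same length as `age`.
#' @export
monthly_death_prob <- function(lt, age, cycles_per_year = 12) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age < lt$age_start[1L])) {
    stop("age below life-table coverage", call. = FALSE)
  }
  idx <- findInterval(age, lt$age_start)   # clamps above terminal band
  q5 <- lt$q5[idx]
  1 - (1 - q5)^(1 / (5 * cycles_per_year))
}

#' Generate a synthetic Gompertz life table
#'
#' Builds a life table from a Gompertz mortality law with hazard
#' `h(t) = a * exp(b * t)` at age `t`, a standard adult-mortality model.
#' The five-year death probability for the band starting at `x` is the
#' closed form `q5 = 1 - exp(-(a/b) * (exp(b*(x+5)) - exp(b*x)))`
#' (or `1 - exp(-5a)` when `b = 0`). A terminal open band with `q5 = 1`
#' is appended at `max_age`. With `b > 0`, `q5` increases strictly with
#' age, as real adult mortality does.
#'
#' @param a Baseline hazard at age 0 (per year); must be positive.
#' @param b Gompertz slope (per year); non-negative.
#' @param max_age Age at which the terminal open band starts (multiple of 5).
#' @param country Label for the generated table.
#' @return A [life_table()] with bands `0-5, 5-10, ..., max_age+`.
#' @export
#' @examples
#' lt <- synth_life_table(a = 0.001, b = 0.09)
#' plot(lt$age_start, lt$q5, type = "s")
synth_life_table <- function(a, b = 0.09, max_age = 110, country = "synthetic") {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("`a` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0) {
    stop("`b` must be a single non-negative number", call. = FALSE)
  }
  if (max_age < 5 || max_age %% 5 != 0) {
    stop("`max_age` must be a positive multiple of 5", call. = FALSE)
  }
  x <- seq(0, max_age - 5, by = 5)
  cum_haz <- if (b == 0) rep(5 * a, length(x)) else
    (a / b) * (exp(b * (x + 5)) - exp(b * x))
  q5 <- 1 - exp(-cum_haz)
  life_table(c(x, max_age), c(x + 5, Inf), c(q5, 1), country = country)
}
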