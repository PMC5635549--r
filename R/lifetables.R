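# Background mortality. A life table is a data frame with integer column
# `age` (contiguous from 0) and `qx`, the annual probability of dying during
# the year of that age; the table closes with qx = 1 at its last age.

.validate_life_table <- function(tab) {
  if (!all(c("age", "qx") %in% names(tab))) {
    stop("life table needs columns `age` and `qx`")
  }
  tab <- tab[order(tab$age), c("age", "qx")]
  if (anyNA(tab$age) || anyNA(tab$qx)) stop("life table contains missing values")
  if (any(tab$age != as.integer(tab$age))) stop("ages must be integers")
  if (tab$age[1] != 0 || any(diff(tab$age) != 1)) {
    stop("ages must run contiguously in 1-year steps from 0")
  }
  if (any(tab$qx < 0 | tab$qx > 1)) stop("qx values must lie in [0, 1]")
  if (tab$qx[nrow(tab)] != 1) {
    stop("the table must close with qx = 1 at its last age (append a closing row)")
  }
  tab$age <- as.integer(tab$age)
  class(tab) <- c("life_table", "data.frame")
  rownames(tab) <- NULL
  tab
}

#' Load a life table from CSV
#'
#' Expects columns `age` (contiguous 1-year ages from 0) and `qx` (annual
#' death probability in `[0, 1]`, closing with 1 at the last age). This is
#' the dialect a published national life table (e.g. a vital-statistics qx
#' column) converts to with a two-column export.
#'
#' @param path CSV file path.
#' @return A validated `life_table`.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  .validate_life_table(utils::read.csv(path))
}

#' Synthetic Gompertz life table
#'
#' Deterministic stand-in for a national life table so every analysis runs
#' without external data: the annual death probability at age `x` is
#' `qx = 1 - exp(-a * exp(b * x))` (a Gompertz hazard integrated over one
#' year at its start-of-year value), capped at 1, with `qx = 1` forced at
#' `max_age`. The defaults (`a = 1e-4`, `b = 0.085`) give a life expectancy
#' at birth in the mid-70s, i.e. the shape and scale of a contemporary US
#' period table without its infant-mortality hook.
#'
#' @param a Baseline hazard at age 0 (must be positive).
#' @param b Log-hazard slope per year of age (nonnegative; 0 gives a
#'   constant `qx`).
#' @param max_age Last age of the table.
#' @return A `life_table`.
#' @export
make_gompertz_lifetable <- function(a = 1e-4, b = 0.085, max_age = 105L) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive")
  if (!is.numeric(b) || b < 0) stop("`b` must be nonnegative")
  ages <- 0:max_age
  qx <- pmin(1, 1 - exp(-a * exp(b * ages)))
  qx[length(qx)] <- 1
  .validate_life_table(data.frame(age = ages, qx = qx))
}

#' Remaining life expectancy from a life table
#'
#' Deterministic cohort expectation of whole years lived from `from_age`:
#' `sum over t >= 1 of prod_{j < t} (1 - qx(from_age + j))`. With
#' `half_cycle = TRUE` a half year is added, crediting the year of death as
#' half-lived; the default counts completed years, matching the simulation's
#' year-granular accounting.
#'
#' @param lt A `life_table`.
#' @param from_age Starting age (must be within the table).
#' @param half_cycle Add the half-cycle correction (default `FALSE`).
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, from_age = 0, half_cycle = FALSE) {
  if (from_age > max(lt$age) || from_age < min(lt$age)) {
    stop("`from_age` is outside the life table")
  }
  q <- lt$qx[lt$age >= from_age]
  sum(cumprod(1 - q)) + if (half_cycle) 0.5 else 0
}

# vectorised qx lookup
lt_qx <- function(lt, ages) {
  idx <- match(ages, lt$age)
  if (anyNA(idx)) {
    stop("age(s) outside the life table: ",
         paste(unique(ages[is.na(idx)]), collapse = ", "))
  }
  lt$qx[idx]
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages 0-%d, e0 = %.1f years\n",
              max(x$age), life_expectancy(x, 0)))
  invisible(x)
}
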