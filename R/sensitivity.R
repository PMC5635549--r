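# One-way (tornado) sensitivity analysis, threshold search, and mortality
# calibration. All reruns share the base seed, so under common random
# numbers the recorded spreads reflect parameter changes, not resampling.

#' One-way sensitivity analysis (tornado data)
#'
#' Re-runs [compare_arms()] with each named parameter pushed to its lower
#' and upper plausible bound (every band of an age-banded parameter moves to
#' its own bound), holding all else at base values and reusing the base
#' seed. Both outcomes are always recorded; rows are sorted by the cost
#' spread, ready for a tornado diagram.
#'
#' @inheritParams compare_arms
#' @param params Parameter names to vary; default: every registry parameter
#'   with a non-degenerate plausible range. Parameters lacking a range are
#'   skipped with a warning.
#' @return Data frame with one row per parameter: bounds, `delta_cost` and
#'   `delta_qaly` at each bound, base outcomes, and spreads.
#' @export
one_way_sa <- function(config, registry = NULL, lifetable = NULL,
                       params = NULL, seed = config$seed) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(lifetable)) lifetable <- lifetable_from_config(config)
  if (is.null(params)) {
    ok <- !is.na(registry$low) & !is.na(registry$high) &
      registry$high > registry$low
    params <- unique(registry$name[ok])
  }
  base <- compare_arms(config, registry, lifetable, seed)
  rows <- list()
  for (nm in params) {
    idx <- which(registry$name == nm)
    if (!length(idx)) stop("unknown parameter: ", nm)
    idx <- idx[order(registry$age_lo[idx])]
    lo <- registry$low[idx]
    hi <- registry$high[idx]
    if (anyNA(lo) || anyNA(hi)) {
      warning("parameter '", nm, "' has no plausible range; skipped")
      next
    }
    at_lo <- compare_arms(config, override(registry, nm, lo), lifetable, seed)
    at_hi <- compare_arms(config, override(registry, nm, hi), lifetable, seed)
    rows[[nm]] <- data.frame(
      param = nm,
      low = lo[1], high = hi[1],
      cost_at_low = at_lo$delta_cost, cost_at_high = at_hi$delta_cost,
      qaly_at_low = at_lo$delta_qaly, qaly_at_high = at_hi$delta_qaly,
      base_cost = base$delta_cost, base_qaly = base$delta_qaly
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(NULL))
  out$cost_spread <- abs(out$cost_at_high - out$cost_at_low)
  out$qaly_spread <- abs(out$qaly_at_high - out$qaly_at_low)
  out <- out[order(-out$cost_spread), ]
  rownames(out) <- NULL
  out
}

#' Threshold analysis by bisection
#'
#' Finds the value of a parameter at which the chosen criterion (net
#' discounted cost difference by default) changes sign, by bisection on the
#' common-random-number estimate at a fixed seed, to a relative tolerance of
#' `tol` of the bracket width. Besides registry parameters, the special
#' names `"program_cost_per_student"` (the per-student charge) and
#' `"school_size"` are supported.
#'
#' @inheritParams compare_arms
#' @param param Parameter to search over.
#' @param bracket Length-2 numeric: the criterion must change sign between
#'   these values (checked; an error reports both endpoint values).
#' @param criterion `"delta_cost"` (default) or `"delta_qaly"`.
#' @param tol Relative bisection tolerance (default 1e-3 of the bracket
#'   width).
#' @return The threshold value.
#' @export
threshold_search <- function(config, registry = NULL, lifetable = NULL,
                             param, bracket, seed = config$seed,
                             criterion = "delta_cost", tol = 1e-3) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(lifetable)) lifetable <- lifetable_from_config(config)
  f <- function(x) {
    if (param == "program_cost_per_student") {
      cfg <- config
      cfg$program_cost_override <- x
      compare_arms(cfg, registry, lifetable, seed)[[criterion]]
    } else if (param == "school_size") {
      cfg <- config
      cfg$school_size <- x
      compare_arms(cfg, registry, lifetable, seed)[[criterion]]
    } else {
      compare_arms(config, override(registry, param, x), lifetable,
                   seed)[[criterion]]
    }
  }
  lo <- min(bracket); hi <- max(bracket)
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf("criterion does not change sign over the bracket: %s(%g) = %g, %s(%g) = %g",
                 criterion, lo, f_lo, criterion, hi, f_hi))
  }
  width <- hi - lo
  while ((hi - lo) > tol * width) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Break-even school size
#'
#' The per-student program cost falls with enrollment while the gross
#' (program-cost-free) savings per student do not depend on it, so the
#' smallest enrollment at which the intervention is cost saving can be found
#' from a single gross-savings run: `delta_cost(s) = gross_delta +
#' program_cost_per_student(s)`.
#'
#' @inheritParams compare_arms
#' @param sizes Integer enrollments scanned (default 1 to 200).
#' @return List with `break_even` (smallest cost-saving enrollment, `NA` if
#'   none in `sizes`), `gross_delta_cost`, and the scanned `table`.
#' @export
break_even_school_size <- function(config, registry = NULL, lifetable = NULL,
                                   seed = config$seed, sizes = 1:200) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(lifetable)) lifetable <- lifetable_from_config(config)
  cfg0 <- config
  cfg0$program_cost_override <- 0
  gross <- compare_arms(cfg0, registry, lifetable, seed)$delta_cost
  per <- program_cost_per_student(config$capacity_cost,
                                  config$capacity_durability,
                                  config$annual_implementation_cost, sizes)
  delta <- gross + per
  hit <- sizes[delta < 0]
  list(break_even = if (length(hit)) min(hit) else NA_integer_,
       gross_delta_cost = gross,
       table = data.frame(school_size = sizes, delta_cost = delta))
}

#' Calibrate the excess-mortality multipliers
#'
#' The disease-specific excess-mortality multipliers are not published
#' inputs; this helper rescales their excess over 1 by a common factor `s`
#' (`m(s) = 1 + s * (m - 1)`) until the simulated remaining life expectancy
#' of an 18-year-old with obesity matches a target (60.1 years against the
#' intended national life table). Deterministic given `seed` via a fixed
#' uniform stream, so the root is well defined at finite `n`.
#'
#' @param registry A `param_registry`.
#' @param lifetable A `life_table`.
#' @param target_le Target remaining life expectancy from `from_age`.
#' @param from_age Starting age of the calibration cohort.
#' @param n Cohort size per evaluation.
#' @param seed Seed for the (common) uniform stream.
#' @param interval Search interval for the scale factor.
#' @param max_age Forced-death age.
#' @return List with `scale`, the rescaled `multipliers`, the calibrated
#'   `registry`, and `achieved_le`.
#' @export
calibrate_mortality_multipliers <- function(registry, lifetable,
                                            target_le = 60.1, from_age = 18L,
                                            n = 20000L, seed = 1L,
                                            interval = c(0.1, 15),
                                            max_age = 105L) {
  mult_names <- c("mult_mortality_cvd", "mult_mortality_diabetes",
                  "mult_mortality_drug")
  base_mult <- vapply(mult_names, function(nm) param_value(registry, nm),
                      numeric(1))
  scaled_registry <- function(s) {
    for (nm in mult_names) {
      registry <- override(registry, nm, 1 + s * (base_mult[[nm]] - 1))
    }
    registry
  }
  obese_cohort <- data.frame(
    age = rep(as.integer(from_age), n), alive = TRUE, obese = TRUE,
    diabetes = FALSE, drug_abuse = FALSE, cvd = FALSE, psych = FALSE,
    judiciary = FALSE, judiciary_last_year = FALSE,
    drug_abuse_last_year = FALSE, obese_last_year = TRUE,
    employed = TRUE, graduated = TRUE
  )
  le_at <- function(s) {
    acc <- simulate_adult_cohort(obese_cohort, scaled_registry(s), lifetable,
                                 seed = seed, max_age = max_age)
    mean(acc$life_years)
  }
  g <- function(s) le_at(s) - target_le
  g_lo <- g(interval[1]); g_hi <- g(interval[2])
  if (sign(g_lo) == sign(g_hi)) {
    stop(sprintf("target life expectancy %.1f not bracketed: LE(%.2f) = %.2f, LE(%.2f) = %.2f; widen `interval` or use a different life table",
                 target_le, interval[1], g_lo + target_le,
                 interval[2], g_hi + target_le))
  }
  root <- stats::uniroot(g, interval, tol = 0.01)
  s <- root$root
  list(scale = s,
       multipliers = 1 + s * (base_mult - 1),
       registry = scaled_registry(s),
       achieved_le = le_at(s))
}
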