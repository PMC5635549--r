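# Parameter registry: one row per model input (age-banded inputs get one row
# per band, sharing a name). Columns mirror the CSV export dialect so that
# write_registry()/load_registry() round-trip losslessly.

.param_roles <- c("baseline_odds", "odds_ratio", "annual_odds",
                  "cost_per_year", "utility", "program_cost",
                  "hazard_multiplier")

.row <- function(name, role, value, low = NA_real_, high = NA_real_,
                 age_lo = NA_real_, age_hi = NA_real_, note = "") {
  data.frame(name = name, role = role, value = value, low = low, high = high,
             age_lo = age_lo, age_hi = age_hi, note = note,
             stringsAsFactors = FALSE)
}

#' Built-in default parameter registry
#'
#' Every model input with its point value and plausible range: childhood
#' "odds ever" inputs, intervention and risk-factor odds ratios, adult annual
#' incidence odds (age-banded for obesity and cardiovascular disease),
#' persistence odds ratios, annual costs (2015 $US), utility weights, program
#' costs, and the excess-mortality hazard multipliers (calibration knobs, not
#' literature inputs). Inputs published without a plausible range are stored
#' with `low == high == value` and treated as fixed in sensitivity analysis.
#'
#' The adult obesity input for ages over 60 is stored as printed (-0.002,
#' below its own lower range 0) and interpreted by the adult phase as a net
#' annual remission probability of 0.002; [validate_registry()] flags it as
#' the one expected range violation.
#'
#' @return A `param_registry` data frame with columns `name`, `role`,
#'   `value`, `low`, `high`, `age_lo`, `age_hi`, `note`.
#' @export
default_registry <- function() {
  rows <- list(
    # -- childhood baseline odds ("odds ever" over the 13-year phase) -------
    .row("odds_academic_child", "baseline_odds", 1.35, 0.7, 2.0,
         note = "odds ever of basic academic proficiency; point prevalence 57.5% (grades 4-12)"),
    .row("odds_obese_child", "baseline_odds", 0.146, 0.09, 0.3,
         note = "odds ever of childhood obesity (BMI >= 95th pct); source text also cites 23.8% cumulative incidence, which 0.146 does not reproduce - stored as printed"),
    .row("odds_low_self_reg", "baseline_odds", 0.33, 0.15, 0.4,
         note = "odds ever of low self-regulation (~25% period prevalence); sampling uses the scenario knob pct_low_self_reg"),
    .row("odds_behavior_problems", "baseline_odds", 0.275, 0.14, 0.4,
         note = "odds ever of behavior problems; period prevalence 21.6%"),
    .row("odds_graduate_hs", "baseline_odds", 2.125, 1.59, 2.66,
         note = "odds of graduating from high school; incidence 68%"),
    .row("odds_drug_abuse_child", "baseline_odds", 0.13, 0.11, 0.15,
         note = "odds of any drug abuse disorder in childhood; point prevalence 11.4%"),
    .row("odds_diabetes_child", "baseline_odds", 0.001, 0, 0.002,
         note = "odds ever of type 2 diabetes as a child"),
    .row("odds_judiciary_child", "baseline_odds", 0.099, 0.074, 0.124,
         note = "odds ever of a judiciary interaction as a child; point prevalence 9%"),
    # -- childhood odds ratios ----------------------------------------------
    .row("or_academic_pc", "odds_ratio", 1.52, 1.0, 2.43,
         note = "academic proficiency given intervention pre-k"),
    .row("or_academic_behavior", "odds_ratio", 0.229, 0.084, 0.621,
         note = "academic proficiency given behavior problems"),
    .row("or_obese_lsr", "odds_ratio", 3.846, 1.36, 4.50,
         note = "childhood obesity given low self-regulation"),
    .row("or_obese_lsr_pc", "odds_ratio", 0.26, 0.08, 0.865,
         note = "childhood obesity given low self-regulation and intervention pre-k"),
    .row("or_obese_nolsr_pc", "odds_ratio", 1.0, 0.82, 1.0,
         note = "childhood obesity given no low self-regulation and intervention pre-k"),
    .row("or_behavior_pc", "odds_ratio", 0.59, 0.41, 0.85,
         note = "behavior problems given intervention pre-k"),
    .row("or_behavior_lsr", "odds_ratio", 3.8, 2.0, 5.5,
         note = "behavior problems given low self-regulation"),
    .row("or_graduate_academic", "odds_ratio", 1.335, 1.0, 4.0,
         note = "graduation given academic proficiency"),
    .row("or_graduate_drug", "odds_ratio", 0.699, 0.584, 0.826,
         note = "graduation given drug abuse"),
    .row("or_graduate_behavior", "odds_ratio", 0.18, 0.1, 1.0,
         note = "graduation given behavior problems"),
    .row("or_drug_behavior", "odds_ratio", 3.8, 1.0, 5.0,
         note = "childhood drug abuse given behavior problems"),
    .row("or_diabetes_obese_child", "odds_ratio", 5.1, 1.51, 17.0,
         note = "childhood diabetes given childhood obesity"),
    .row("or_judiciary_drug_child", "odds_ratio", 5.7, 2.30, 15.05,
         note = "childhood judiciary interaction given drug abuse"),
    .row("or_judiciary_behavior_child", "odds_ratio", 2.925, 1.300, 6.375,
         note = "childhood judiciary interaction given behavior problems"),
    # -- adult annual odds ---------------------------------------------------
    .row("odds_obesity_adult", "annual_odds",
         c(0.003, 0.005, -0.002), c(0, 0.001, 0), c(0.064, 0.01, 0.005),
         age_lo = c(18, 40, 60), age_hi = c(39, 59, 105),
         note = "annual odds of developing obesity (BMI > 30); -0.002 in the oldest band read as net annual remission of 0.002"),
    .row("odds_drug_adult", "annual_odds", 0.007, 0.002, 0.013,
         note = "annual odds of adult drug abuse (any alcohol use/dependence); lifetime cumulative incidence 26.6%"),
    .row("odds_diabetes_adult", "annual_odds", 0.0069, 0.006, 0.008,
         note = "annual odds of adult diabetes; cumulative incidence 6.9 per 1000 (ages 18-79)"),
    .row("odds_employment", "baseline_odds", 12.7, 9.52, 15.87,
         note = "odds of employment; point prevalence 92.7%, fixed through adulthood unless a judiciary interaction forces a redraw"),
    .row("or_diabetes_obese_adult", "odds_ratio", 7.37, 6.39, 8.50,
         note = "adult diabetes given obesity"),
    .row("odds_judiciary_adult", "annual_odds", 0.002, 0, 0.005,
         note = "annual odds of newly interacting with the judiciary system (ever-prison lifetime cumulative incidence 4.5%)"),
    .row("odds_psych_adult", "annual_odds", 0.007, 0.005, 0.009,
         note = "annual odds of a new psychiatric (mood) disorder"),
    .row("odds_cvd_adult", "annual_odds",
         c(0.004, 0.007, 0.015, 0.028, 0.052, 0.075),
         c(0.002, 0.006, 0.010, 0.020, 0.045, 0.07),
         c(0.006, 0.008, 0.022, 0.035, 0.060, 0.08),
         age_lo = c(18, 45, 55, 65, 75, 85),
         age_hi = c(44, 54, 64, 74, 84, 105),
         note = "annual odds of cardiovascular disease by age band"),
    .row("or_cvd_diabetes", "odds_ratio", 2.3, 1.5, 3.5,
         note = "cardiovascular disease given diabetes"),
    .row("or_cvd_obese", "odds_ratio", 2.3, 1.5, 3.5,
         note = "cardiovascular disease given obesity; assumed equal to the diabetes risk"),
    .row("or_psych_drug", "odds_ratio", 4.5, 3.36, 7.38,
         note = "psychiatric disorder given drug abuse"),
    .row("or_judiciary_drug_adult", "odds_ratio", 4.14, 1.2, 5.5,
         note = "adult judiciary interaction given drug abuse"),
    .row("or_judiciary_recidivism", "odds_ratio", 227, 50, 250,
         note = "judiciary interaction given an interaction in the previous year"),
    .row("or_employment_graduate", "odds_ratio", 1.88, 1.5, 3.0,
         note = "employment given high-school graduation"),
    .row("or_employment_judiciary", "odds_ratio", 0.029, 0.005, 0.1,
         note = "employment given a judiciary interaction in the previous year"),
    .row("or_drug_persistence", "odds_ratio", 47.6, 23, 5571,
         note = "drug use given drug abuse in the previous year; printed range is ambiguous in the source table (digits '235571'), stored as 23-5571"),
    .row("or_obese_persistence", "odds_ratio", 331, 331, 331,
         note = "obesity given obesity in the previous year; back-calculated from odds 0.007 of non-persistence; no printed range, treated as fixed"),
    # -- annual costs, 2015 $US ---------------------------------------------
    .row("cost_drug_treatment", "cost_per_year", 1000, 500, 1500,
         note = "annual drug abuse treatment cost"),
    .row("cost_drug_complication", "cost_per_year", 21483, 10742, 32225,
         note = "annual drug abuse complication (psychiatric sequela) cost"),
    .row("cost_diabetes_treatment", "cost_per_year", 9975, 4988, 14963,
         note = "annual diabetes treatment cost"),
    .row("cost_diabetes_complication", "cost_per_year", 1575, 788, 2363,
         note = "annual diabetes complication cost"),
    .row("cost_obesity_treatment", "cost_per_year", 0, 0, 0,
         note = "annual obesity treatment cost"),
    .row("cost_obesity_complication", "cost_per_year", 732, 366, 1098,
         note = "annual obesity complication cost"),
    .row("cost_incarceration", "cost_per_year", 28893, 14447, 43340,
         note = "annual judiciary system cost of incarceration"),
    .row("cost_unemployment", "cost_per_year", 33160, 16580, 49740,
         note = "annual unemployment opportunity cost"),
    # -- program costs (no printed ranges; varied via scenario knobs) -------
    .row("cost_pc_annual_per_child", "program_cost", 500, 500, 500,
         note = "ongoing program cost per child per year; fixed (no printed range)"),
    .row("cost_pc_capacity_per_school", "program_cost", 100000, 100000, 100000,
         note = "program capacity-building cost per school; fixed (no printed range); scenario costing uses the 200k/2yr + 40k/yr schedule"),
    # -- utility weights -----------------------------------------------------
    .row("utility_diabetes", "utility", 0.690, 0.690, 0.690,
         note = "utility of having diabetes"),
    .row("utility_diabetes_complications", "utility", 0.350, 0.350, 0.350,
         note = "utility of having complications of diabetes"),
    .row("utility_drug", "utility", 0.670, 0.670, 0.670,
         note = "utility of drug abuse"),
    .row("utility_drug_complications", "utility", 0.600, 0.600, 0.600,
         note = "utility of having complications of drug abuse"),
    .row("utility_obese", "utility", 0.710, 0.710, 0.710,
         note = "utility of being obese"),
    .row("utility_obesity_complications", "utility", 0.500, 0.500, 0.500,
         note = "utility of having complications of obesity"),
    .row("utility_prison", "utility", 0.725, 0.725, 0.725,
         note = "utility of being in prison"),
    # -- excess-mortality multipliers (model calibration knobs) -------------
    .row("mult_mortality_cvd", "hazard_multiplier", 2.0, 1.0, 4.0,
         note = "background death-probability multiplier while cardiovascular disease is active; calibration knob, not a published input"),
    .row("mult_mortality_diabetes", "hazard_multiplier", 1.5, 1.0, 3.0,
         note = "death-probability multiplier while diabetic; calibration knob"),
    .row("mult_mortality_drug", "hazard_multiplier", 1.5, 1.0, 3.0,
         note = "death-probability multiplier while abusing drugs; calibration knob")
  )
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  class(reg) <- c("param_registry", "data.frame")
  reg
}

#' Load a parameter registry
#'
#' With `source = NULL` returns the built-in defaults. A `.csv` path is read
#' in the [write_registry()] dialect; every default parameter name must be
#' present, and rows missing a plausible range default to +/-50% of the point
#' value with a warning (utility ranges are clipped to `[0, 1]`). A
#' `.yaml`/`.yml`/`.json` path is read as a scenario configuration file and
#' its `parameter_overrides` section is applied to the defaults.
#'
#' @param source `NULL`, or path to a registry CSV or a config file.
#' @return A `param_registry`.
#' @export
load_registry <- function(source = NULL) {
  if (is.null(source) || identical(source, "default")) return(default_registry())
  if (!file.exists(source)) stop("registry source not found: ", source)
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("yaml", "yml", "json")) {
    return(load_scenario_config(source)$registry)
  }
  if (ext != "csv") stop("unsupported registry source (expected .csv, .yaml or .json): ", source)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  needed <- c("name", "role", "value", "low", "high", "age_lo", "age_hi", "note")
  if (!all(needed %in% names(tab))) {
    stop("registry CSV must have columns: ", paste(needed, collapse = ", "))
  }
  tab <- tab[, needed]
  tab$note[is.na(tab$note)] <- ""
  defaults <- default_registry()
  missing <- setdiff(defaults$name, tab$name)
  if (length(missing)) {
    stop("registry is missing required parameter(s): ", paste(missing, collapse = ", "))
  }
  no_range <- is.na(tab$low) | is.na(tab$high)
  if (any(no_range)) {
    warning("no plausible range for ", sum(no_range),
            " parameter(s); defaulting to +/-50% of the point value: ",
            paste(unique(tab$name[no_range]), collapse = ", "))
    tab$low[no_range] <- tab$value[no_range] * 0.5
    tab$high[no_range] <- tab$value[no_range] * 1.5
    util <- no_range & tab$role == "utility"
    tab$high[util] <- pmin(tab$high[util], 1)
  }
  class(tab) <- c("param_registry", "data.frame")
  bad_bands <- .band_violations(tab)
  if (length(bad_bands)) stop("malformed age bands: ", paste(bad_bands, collapse = "; "))
  tab
}

#' Export a registry to CSV
#'
#' @param registry A `param_registry`.
#' @param path Output file; one row per parameter (per band for age-banded
#'   parameters), columns `name, role, value, low, high, age_lo, age_hi, note`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Override one parameter value
#'
#' Returns a modified copy; the input registry is untouched. Age-banded
#' parameters take either a vector with one value per band (bands in
#' ascending age order) or an `age` selecting a single band.
#'
#' @param registry A `param_registry`.
#' @param name Parameter name.
#' @param value Replacement value(s).
#' @param age Optional age (years) selecting one band of an age-banded
#'   parameter.
#' @return The modified registry.
#' @export
override <- function(registry, name, value, age = NULL) {
  idx <- which(registry$name == name)
  if (!length(idx)) {
    stop("unknown parameter '", name, "'. Valid names: ",
         paste(sort(unique(registry$name)), collapse = ", "))
  }
  if (length(idx) > 1L) {
    idx <- idx[order(registry$age_lo[idx])]
    if (!is.null(age)) {
      sel <- registry$age_lo[idx] <= age & age <= registry$age_hi[idx]
      if (!any(sel)) stop("age ", age, " outside the bands of '", name, "'")
      idx <- idx[sel]
      if (length(value) != 1L) stop("supply a single value for one band")
    } else if (length(value) != length(idx)) {
      stop("'", name, "' is age-banded (", length(idx),
           " bands); supply one value per band or an `age`")
    }
  } else if (length(value) != 1L) {
    stop("supply a single value for '", name, "'")
  }
  registry$value[idx] <- value
  registry
}

# band structure checks shared by load/validate; returns messages
.band_violations <- function(registry) {
  out <- character()
  for (nm in unique(registry$name[!is.na(registry$age_lo)])) {
    rows <- registry[registry$name == nm & !is.na(registry$age_lo), , drop = FALSE]
    rows <- rows[order(rows$age_lo), , drop = FALSE]
    if (rows$age_lo[1] != 18) {
      out <- c(out, paste0(nm, ": bands must start at age 18"))
    }
    if (nrow(rows) > 1L && any(rows$age_lo[-1] != rows$age_hi[-nrow(rows)] + 1)) {
      out <- c(out, paste0(nm, ": bands must tile the age range without gaps or overlap"))
    }
    if (rows$age_hi[nrow(rows)] < 105) {
      out <- c(out, paste0(nm, ": bands must cover ages up to 105"))
    }
  }
  out
}

#' Validate a parameter registry
#'
#' Checks every registry invariant and reports violations as human-readable
#' strings (an empty result means the registry is clean). The default
#' registry reports exactly one known flag: the adult obesity input for ages
#' over 60, whose printed point value -0.002 lies below its lower range 0
#' (interpreted downstream as net remission).
#'
#' @param registry A `param_registry`.
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_registry <- function(registry) {
  out <- character()
  bad_role <- !registry$role %in% .param_roles
  if (any(bad_role)) {
    out <- c(out, paste0(registry$name[bad_role], ": unknown role '",
                         registry$role[bad_role], "'"))
  }
  has_range <- !is.na(registry$low) & !is.na(registry$high)
  rev_range <- has_range & registry$low > registry$high
  if (any(rev_range)) {
    out <- c(out, paste0(registry$name[rev_range], ": low exceeds high"))
  }
  off <- has_range & !rev_range &
    (registry$value < registry$low | registry$value > registry$high)
  if (any(off)) {
    out <- c(out, paste0(registry$name[off], ": value ", registry$value[off],
                         " outside plausible range [", registry$low[off], ", ",
                         registry$high[off], "]"))
  }
  util <- registry$role == "utility"
  bad_util <- util & (registry$value < 0 | registry$value > 1)
  if (any(bad_util)) {
    out <- c(out, paste0(registry$name[bad_util], ": utility ",
                         registry$value[bad_util], " outside [0, 1]"))
  }
  c(out, .band_violations(registry))
}

#' Point value of a scalar (non-banded) parameter
#'
#' @param registry A `param_registry`.
#' @param name Parameter name.
#' @return The stored value.
#' @export
param_value <- function(registry, name) {
  idx <- which(registry$name == name)
  if (!length(idx)) stop("unknown parameter: ", name)
  if (length(idx) > 1L) stop("'", name, "' is age-banded; use param_at_age()")
  registry$value[idx]
}

#' Value of a (possibly age-banded) parameter at given ages
#'
#' @param registry A `param_registry`.
#' @param name Parameter name.
#' @param ages Integer ages (years), vectorised.
#' @return Numeric vector of values, one per age.
#' @export
param_at_age <- function(registry, name, ages) {
  idx <- which(registry$name == name)
  if (!length(idx)) stop("unknown parameter: ", name)
  if (length(idx) == 1L && is.na(registry$age_lo[idx])) {
    return(rep(registry$value[idx], length(ages)))
  }
  out <- rep(NA_real_, length(ages))
  for (i in idx) {
    sel <- ages >= registry$age_lo[i] & ages <= registry$age_hi[i]
    out[sel] <- registry$value[i]
  }
  if (anyNA(out)) {
    stop("age(s) ", paste(unique(ages[is.na(out)]), collapse = ", "),
         " outside the bands of '", name, "'")
  }
  out
}

#' @export
print.param_registry <- function(x, ...) {
  cat("Parameter registry:", length(unique(x$name)), "parameters (",
      nrow(x), "rows incl. age bands )\n")
  v <- validate_registry(x)
  if (length(v)) cat("Flags:\n", paste(" -", v, collapse = "\n"), "\n")
  NextMethod()
}
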