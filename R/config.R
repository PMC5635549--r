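#' Scenario configuration
#'
#' Bundles the run-level knobs of the simulation: arm, cohort size, seed,
#' discounting, program costing, and the structural switches the model
#' exposes where the published description is ambiguous.
#'
#' @param arm `"standard"` or `"intervention"`.
#' @param n_individuals Cohort size (base case 100,000).
#' @param seed Integer master seed.
#' @param discount_rate Annual discount rate (base case 0.05).
#' @param max_age Maximum age in years; anyone alive at `max_age` dies at
#'   cycle end (default 105).
#' @param school_size Pre-k students served per school per year (base 72).
#' @param pct_low_self_reg Fraction of children entering pre-k with low
#'   self-regulation (base 0.25).
#' @param capacity_cost Capacity-building investment in $ (base 200,000,
#'   covering the first 2 years of implementation).
#' @param capacity_durability Years the capacity investment lasts (base 5,
#'   minimum 2).
#' @param annual_implementation_cost $ per year after the first 2 years
#'   (base 40,000).
#' @param life_table_source `"synthetic"` for the built-in Gompertz life
#'   table, or a path to a life-table CSV (columns `age`, `qx`).
#' @param obesity_or_mode How the intervention odds ratio for obesity in the
#'   low-self-regulation subgroup combines with the subgroup risk OR:
#'   `"multiplicative"` (default; 0.146 x 3.846 x 0.26) or `"substitute"`
#'   (0.146 x 0.26).
#' @param cvd_both_mode Cardiovascular risk when both obesity and diabetes
#'   are present: `"single"` (default; one OR of 2.3, diabetes taking
#'   precedence) or `"multiplicative"`.
#' @param charge_child_judiciary If `TRUE`, a childhood judiciary interaction
#'   is charged one discounted year of incarceration cost (default `FALSE`).
#' @param program_cost_override Optional per-student program charge in $
#'   replacing the capacity/implementation costing (used by threshold
#'   analysis); `NULL` to compute from the costing knobs.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(arm = c("standard", "intervention"),
                            n_individuals = 100000L,
                            seed = 1L,
                            discount_rate = 0.05,
                            max_age = 105L,
                            school_size = 72L,
                            pct_low_self_reg = 0.25,
                            capacity_cost = 200000,
                            capacity_durability = 5,
                            annual_implementation_cost = 40000,
                            life_table_source = "synthetic",
                            obesity_or_mode = c("multiplicative", "substitute"),
                            cvd_both_mode = c("single", "multiplicative"),
                            charge_child_judiciary = FALSE,
                            program_cost_override = NULL) {
  arm <- match.arg(arm)
  obesity_or_mode <- match.arg(obesity_or_mode)
  cvd_both_mode <- match.arg(cvd_both_mode)
  stopifnot(
    "n_individuals must be >= 1" = n_individuals >= 1,
    "discount_rate must lie in [0, 1)" = discount_rate >= 0 && discount_rate < 1,
    "school_size must be >= 1" = school_size >= 1,
    "capacity_durability must be >= 2 (the capacity cost covers the first 2 years)" =
      capacity_durability >= 2,
    "pct_low_self_reg must lie in [0, 1]" =
      pct_low_self_reg >= 0 && pct_low_self_reg <= 1,
    "max_age must exceed 18" = max_age > 18
  )
  structure(
    list(arm = arm, n_individuals = as.integer(n_individuals),
         seed = as.integer(seed), discount_rate = discount_rate,
         max_age = as.integer(max_age), school_size = school_size,
         pct_low_self_reg = pct_low_self_reg, capacity_cost = capacity_cost,
         capacity_durability = capacity_durability,
         annual_implementation_cost = annual_implementation_cost,
         life_table_source = life_table_source,
         obesity_or_mode = obesity_or_mode, cvd_both_mode = cvd_both_mode,
         charge_child_judiciary = charge_child_judiciary,
         program_cost_override = program_cost_override),
    class = "scenario_config"
  )
}

#' Load a scenario configuration file
#'
#' Reads a YAML or JSON file with two top-level sections: `scenario`
#' (arguments of [scenario_config()]) and `parameter_overrides` (named
#' parameter values applied to the default registry via [override()]).
#' Unknown keys in either section are rejected.
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @param registry Registry the overrides are applied to (default: built-in).
#' @return List with elements `config` (a `scenario_config`) and `registry`.
#' @export
load_scenario_config <- function(path, registry = default_registry()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  if (is.null(obj)) obj <- list()
  unknown <- setdiff(names(obj), c("scenario", "parameter_overrides"))
  if (length(unknown)) {
    stop("unknown top-level config section(s): ", paste(unknown, collapse = ", "))
  }
  scen <- obj$scenario
  if (is.null(scen)) scen <- list()
  bad <- setdiff(names(scen), names(formals(scenario_config)))
  if (length(bad)) stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
  config <- do.call(scenario_config, scen)
  ov <- obj$parameter_overrides
  if (!is.null(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop("parameter_overrides must be a named mapping")
    }
    for (nm in names(ov)) registry <- override(registry, nm, unlist(ov[[nm]]))
  }
  list(config = config, registry = registry)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$arm, "arm, n =", x$n_individuals, ", seed", x$seed, "\n")
  cat(sprintf("  discount %.1f%%/yr, max age %d, life table: %s\n",
              100 * x$discount_rate, x$max_age, x$life_table_source))
  cat(sprintf("  school size %s students/yr, %.0f%% low self-regulation\n",
              format(x$school_size), 100 * x$pct_low_self_reg))
  cat(sprintf("  program: $%s capacity / %s yr + $%s/yr\n",
              format(x$capacity_cost, big.mark = ","), x$capacity_durability,
              format(x$annual_implementation_cost, big.mark = ",")))
  invisible(x)
}
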