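# Discounted cost/QALY accounting, from a societal perspective: disease
# treatment, sequela (complication) costs, incarceration, and the
# opportunity cost of unemployment. Utilities follow the minimum-utility
# rule for joint conditions; unemployment never reduces utility (its cost is
# already counted, and double-counting is avoided).

#' Annual societal cost of an adult state
#'
#' Sums, for every active condition: treatment cost for obesity ($0),
#' diabetes and drug abuse; complication costs attached to sequela flags
#' (psychiatric disorder carries the drug complication cost; cardiovascular
#' disease carries the diabetes complication cost when the person is
#' diabetic, otherwise the obesity complication cost); incarceration cost in
#' a judiciary-interaction year; and the unemployment opportunity cost when
#' not employed.
#'
#' @param state Adult state data frame (all rows alive).
#' @param registry A `param_registry`.
#' @return Cost in $ per year, one per row.
#' @export
annual_cost <- function(state, registry) {
  if (any(!state$alive)) stop("annual cost is undefined for dead states")
  pv <- function(nm) param_value(registry, nm)
  cvd_complication <- ifelse(state$diabetes,
                             pv("cost_diabetes_complication"),
                             pv("cost_obesity_complication"))
  state$drug_abuse * pv("cost_drug_treatment") +
    state$diabetes * pv("cost_diabetes_treatment") +
    state$obese * pv("cost_obesity_treatment") +
    state$psych * pv("cost_drug_complication") +
    state$cvd * cvd_complication +
    state$judiciary * pv("cost_incarceration") +
    (!state$employed) * pv("cost_unemployment")
}

#' Annual utility of an adult state
#'
#' 1 when no condition applies; otherwise the minimum utility over the
#' active conditions: obesity 0.71, diabetes 0.69, drug abuse 0.67,
#' psychiatric sequela 0.60, cardiovascular sequela 0.35 with diabetes /
#' 0.50 without, prison 0.725 (in the year of the interaction only).
#' Unemployment does not reduce utility.
#'
#' @inheritParams annual_cost
#' @return Utility in `[0, 1]`, one per row.
#' @export
annual_utility <- function(state, registry) {
  if (any(!state$alive)) stop("utility is undefined for dead states")
  pv <- function(nm) param_value(registry, nm)
  pmin(
    ifelse(state$obese, pv("utility_obese"), 1),
    ifelse(state$diabetes, pv("utility_diabetes"), 1),
    ifelse(state$drug_abuse, pv("utility_drug"), 1),
    ifelse(state$psych, pv("utility_drug_complications"), 1),
    ifelse(state$cvd,
           ifelse(state$diabetes, pv("utility_diabetes_complications"),
                  pv("utility_obesity_complications")),
           1),
    ifelse(state$judiciary, pv("utility_prison"), 1)
  )
}

#' Create an outcome accumulator
#'
#' @param n Number of individuals tracked.
#' @return List of class `outcome_accumulator` with zeroed vectors
#'   `disc_cost` ($), `disc_qaly` (QALYs) and `life_years`.
#' @export
new_accumulator <- function(n = 1L) {
  structure(list(disc_cost = numeric(n), disc_qaly = numeric(n),
                 life_years = numeric(n)),
            class = "outcome_accumulator")
}

#' Accrue one lived year into an accumulator
#'
#' Adds `cost * d` and `utility * d` with `d = discount_factor(rate,
#' years_since_entry)`, and one undiscounted life year.
#'
#' @param acc An `outcome_accumulator`.
#' @param cost Cost in $ for the year (vectorised).
#' @param utility Utility in `[0, 1]` for the year (vectorised).
#' @param years_since_entry Whole years since model entry (0 for the first
#'   year).
#' @param rate Annual discount rate.
#' @return The updated accumulator.
#' @export
accumulate <- function(acc, cost, utility, years_since_entry, rate) {
  if (any(utility < 0 | utility > 1)) stop("utility must lie in [0, 1]")
  d <- discount_factor(rate, years_since_entry)
  acc$disc_cost <- acc$disc_cost + cost * d
  acc$disc_qaly <- acc$disc_qaly + utility * d
  acc$life_years <- acc$life_years + 1
  acc
}

#' Amortized program cost per student
#'
#' The capacity-building investment covers the first two years of
#' implementation; each further year of its lifetime costs the annual
#' implementation amount. The total is spread over all students served:
#' `(capacity_cost + (durability - 2) * annual_cost) /
#' (students_per_year * durability)`. The base-case inputs ($200,000, 5
#' years, $40,000/yr, 72 students/yr) give $320,000 for 360 students, i.e.
#' $888.89 per student.
#'
#' @param capacity_cost Capacity-building investment in $.
#' @param durability Years the investment lasts (`>= 2`).
#' @param annual_cost Implementation cost in $/yr after the first 2 years.
#' @param students_per_year Students served per year (`>= 1`).
#' @return Cost in $ per student.
#' @export
program_cost_per_student <- function(capacity_cost, durability, annual_cost,
                                     students_per_year) {
  if (any(durability < 2)) {
    stop("`durability` must be at least 2: the capacity cost covers the first 2 years")
  }
  if (any(students_per_year < 1)) stop("`students_per_year` must be at least 1")
  (capacity_cost + (durability - 2) * annual_cost) /
    (students_per_year * durability)
}
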