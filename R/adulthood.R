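# Adult phase: annual cycles from age 18 until death. Each year applies, in
# fixed order: background death (scaled by condition multipliers), obesity
# (with persistence or, over 60, net remission), diabetes (absorbing), drug
# abuse (with persistence), cardiovascular disease (absorbing sequela of
# obesity/diabetes), psychiatric disorder (absorbing sequela of drug abuse),
# judiciary interaction (with recidivism), and employment (fixed unless
# re-drawn the year after a judiciary interaction). Death comes first so no
# costs or utilities are accrued in the year of death.

.adult_fields <- c("age", "alive", "obese", "diabetes", "drug_abuse", "cvd",
                   "psych", "judiciary", "judiciary_last_year",
                   "drug_abuse_last_year", "obese_last_year", "employed",
                   "graduated")

#' Initialize adult states from childhood profiles
#'
#' Disease statuses (obesity, diabetes, drug abuse) carry over from
#' childhood; sequelae start inactive; employment is drawn once from the
#' employment odds, adjusted by OR 1.88 for graduates. Memory flags for
#' obesity and drug abuse are seeded with the carried statuses so the
#' persistence odds ratios apply from the first adult year; the judiciary
#' memory starts clear (a childhood interaction occurred somewhere in a
#' 13-year window, not necessarily the prior year).
#'
#' @param profile Complete childhood profile(s) from [draw_child_profile()].
#' @param registry A `param_registry`.
#' @param u Optional uniforms (one per row) for the employment draw.
#' @return Data frame of adult states at age 18, one row per profile.
#' @export
init_adult_state <- function(profile, registry, u = NULL) {
  n <- nrow(profile)
  if (anyNA(profile[setdiff(names(profile), "arm")])) {
    stop("profile has unset fields")
  }
  if (is.null(u)) u <- stats::runif(n)
  emp_odds <- param_value(registry, "odds_employment") *
    ifelse(profile$graduated, param_value(registry, "or_employment_graduate"), 1)
  data.frame(
    age = rep(18L, n), alive = rep(TRUE, n),
    obese = profile$obese, diabetes = profile$diabetes,
    drug_abuse = profile$drug_abuse,
    cvd = rep(FALSE, n), psych = rep(FALSE, n),
    judiciary = rep(FALSE, n), judiciary_last_year = rep(FALSE, n),
    drug_abuse_last_year = profile$drug_abuse,
    obese_last_year = profile$obese,
    employed = u < odds_to_prob(emp_odds),
    graduated = profile$graduated
  )
}

#' Excess-mortality multiplier of a state
#'
#' Product of the configured hazard multipliers of the active conditions
#' (defaults: cardiovascular disease 2.0, diabetes 1.5, drug abuse 1.5);
#' 1.0 when none is active. The multipliers scale the background annual
#' death probability, which is then capped at 1.
#'
#' @param state Adult state data frame (all rows alive).
#' @param registry A `param_registry`.
#' @return Positive multiplier, one per row.
#' @export
mortality_multiplier <- function(state, registry) {
  if (any(!state$alive)) stop("mortality multiplier is undefined for dead states")
  .mortality_multiplier_vec(state, registry)
}

.mortality_multiplier_vec <- function(state, registry) {
  ifelse(state$cvd, param_value(registry, "mult_mortality_cvd"), 1) *
    ifelse(state$diabetes, param_value(registry, "mult_mortality_diabetes"), 1) *
    ifelse(state$drug_abuse, param_value(registry, "mult_mortality_drug"), 1)
}

#' Advance adult states by one year
#'
#' Applies the fixed within-year update order documented above. Transitions
#' later in the order condition on the statuses already updated this year
#' (e.g. diabetes incidence uses this year's obesity status), and the
#' persistence/recidivism odds ratios condition on last year's statuses.
#' All rows must be alive; use the engine for mixed cohorts.
#'
#' @param state Adult state data frame (all rows alive).
#' @param registry A `param_registry`.
#' @param lifetable A `life_table` covering the cohort's ages.
#' @param u Optional `n x 8` matrix of uniforms, one column per decision in
#'   update order (death, obesity, diabetes, drug abuse, cvd, psychiatric,
#'   judiciary, employment); drawn from the current RNG stream when `NULL`.
#' @param cvd_both_mode `"single"` (default) or `"multiplicative"` handling
#'   of simultaneous obesity and diabetes.
#' @param max_age Anyone at or beyond this age dies this cycle.
#' @return The updated states (age advanced for survivors; decedents frozen
#'   with `alive = FALSE`).
#' @export
step_adult_year <- function(state, registry, lifetable, u = NULL,
                            cvd_both_mode = c("single", "multiplicative"),
                            max_age = 105L) {
  if (any(!state$alive)) stop("cannot step a dead state")
  cvd_both_mode <- match.arg(cvd_both_mode)
  if (is.null(u)) u <- matrix(stats::runif(nrow(state) * 8L), ncol = 8L)
  .step_year(state, registry, lifetable, u, cvd_both_mode, max_age)
}

# Internal stepper: tolerates dead rows (frozen untouched) so the engine can
# keep a fixed-size cohort frame and positionally aligned uniforms.
.step_year <- function(state, registry, lifetable, u,
                       cvd_both_mode = "single", max_age = 105L) {
  n <- nrow(state)
  stopifnot(nrow(u) == n, ncol(u) == 8L)
  pv <- function(nm) param_value(registry, nm)
  alive0 <- state$alive
  age <- state$age
  grad <- state$graduated
  obese0 <- state$obese; dia0 <- state$diabetes; drug0 <- state$drug_abuse
  cvd0 <- state$cvd; psych0 <- state$psych; jud0 <- state$judiciary

  # (1) death: background qx times condition multipliers, capped at 1
  q <- rep(1, n)
  in_table <- age <= max(lifetable$age)
  q[alive0 & in_table] <- lt_qx(lifetable, age[alive0 & in_table])
  q <- pmin(1, q * .mortality_multiplier_vec(state, registry))
  q[age >= max_age] <- 1
  live <- alive0 & !(u[, 1L] < q)

  # (2) obesity: persistence OR for last year's obese; over-60 band encodes
  #     zero incidence plus net remission
  ob_band <- param_at_age(registry, "odds_obesity_adult", pmin(age, 105L))
  or_op <- pv("or_obese_persistence")
  inc_p <- ifelse(ob_band < 0, 0, ob_band / (1 + ob_band))
  stay_p <- ifelse(ob_band < 0, 1 + ob_band,
                   (ob_band * or_op) / (1 + ob_band * or_op))
  p_ob <- ifelse(obese0, stay_p, inc_p)
  obese1 <- obese0
  obese1[live] <- u[live, 2L] < p_ob[live]

  # (3) diabetes, absorbing
  o_dia <- pv("odds_diabetes_adult") *
    ifelse(obese1, pv("or_diabetes_obese_adult"), 1)
  dia1 <- dia0
  dia1[live] <- dia0[live] | (u[live, 3L] < odds_to_prob(o_dia[live]))

  # (4) drug abuse, with persistence
  o_drug <- pv("odds_drug_adult") *
    ifelse(drug0, pv("or_drug_persistence"), 1)
  drug1 <- drug0
  drug1[live] <- u[live, 4L] < odds_to_prob(o_drug[live])

  # (5) cardiovascular disease, absorbing sequela of obesity/diabetes
  cvd_band <- param_at_age(registry, "odds_cvd_adult", pmin(age, 105L))
  or_cvd <- if (cvd_both_mode == "multiplicative") {
    ifelse(dia1, pv("or_cvd_diabetes"), 1) * ifelse(obese1, pv("or_cvd_obese"), 1)
  } else {
    ifelse(dia1, pv("or_cvd_diabetes"), ifelse(obese1, pv("or_cvd_obese"), 1))
  }
  o_cvd <- cvd_band * or_cvd
  cvd1 <- cvd0
  cvd1[live] <- cvd0[live] | (u[live, 5L] < odds_to_prob(o_cvd[live]))

  # (6) psychiatric disorder, absorbing sequela of drug abuse
  o_psy <- pv("odds_psych_adult") * ifelse(drug1, pv("or_psych_drug"), 1)
  psych1 <- psych0
  psych1[live] <- psych0[live] | (u[live, 6L] < odds_to_prob(o_psy[live]))

  # (7) judiciary interaction, with recidivism
  o_jud <- pv("odds_judiciary_adult") *
    ifelse(drug1, pv("or_judiciary_drug_adult"), 1) *
    ifelse(jud0, pv("or_judiciary_recidivism"), 1)
  jud1 <- jud0
  jud1[live] <- u[live, 7L] < odds_to_prob(o_jud[live])

  # (8) employment: fixed, except re-drawn the year after an interaction
  o_emp <- pv("odds_employment") *
    ifelse(grad, pv("or_employment_graduate"), 1) *
    pv("or_employment_judiciary")
  emp1 <- state$employed
  redraw <- live & jud0
  emp1[redraw] <- u[redraw, 8L] < odds_to_prob(o_emp[redraw])

  state$judiciary_last_year[live] <- jud0[live]
  state$drug_abuse_last_year[live] <- drug0[live]
  state$obese_last_year[live] <- obese0[live]
  state$obese <- obese1
  state$diabetes <- dia1
  state$drug_abuse <- drug1
  state$cvd <- cvd1
  state$psych <- psych1
  state$judiciary <- jud1
  state$employed <- emp1
  state$age[live] <- age[live] + 1L
  state$alive <- live
  state
}
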