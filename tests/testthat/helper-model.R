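# Shared fixtures, built in code.

# Life table with constant annual death probability q (closing at 1).
flat_lifetable <- function(q, max_age = 105L) {
  qx <- rep(q, max_age + 1L)
  qx[max_age + 1L] <- 1
  prekCEA:::.validate_life_table(data.frame(age = 0:max_age, qx = qx))
}

# No background mortality until the forced closing age.
deathless_lifetable <- function(max_age = 105L) flat_lifetable(0, max_age)

# Registry with every disease/event incidence forced to zero (graduation and
# employment odds untouched; they do not affect survival).
zero_disease_registry <- function(reg = default_registry()) {
  for (nm in c("odds_academic_child", "odds_obese_child",
               "odds_behavior_problems", "odds_drug_abuse_child",
               "odds_diabetes_child", "odds_judiciary_child",
               "odds_drug_adult", "odds_diabetes_adult",
               "odds_judiciary_adult", "odds_psych_adult")) {
    reg <- override(reg, nm, 0)
  }
  reg <- override(reg, "odds_obesity_adult", c(0, 0, 0))
  override(reg, "odds_cvd_adult", rep(0, 6))
}

# Registry in which the intervention has no effect.
null_intervention_registry <- function(reg = default_registry()) {
  for (nm in c("or_behavior_pc", "or_academic_pc", "or_obese_lsr_pc",
               "or_obese_nolsr_pc")) {
    reg <- override(reg, nm, 1)
  }
  reg
}

# Adult state frame with overridable fields.
make_adult_state <- function(n = 1L, age = 30L, obese = FALSE,
                             diabetes = FALSE, drug_abuse = FALSE,
                             cvd = FALSE, psych = FALSE, judiciary = FALSE,
                             judiciary_last_year = FALSE,
                             drug_abuse_last_year = FALSE,
                             obese_last_year = FALSE, employed = TRUE,
                             graduated = TRUE, alive = TRUE) {
  data.frame(age = rep(as.integer(age), n), alive = alive, obese = obese,
             diabetes = diabetes, drug_abuse = drug_abuse, cvd = cvd,
             psych = psych, judiciary = judiciary,
             judiciary_last_year = judiciary_last_year,
             drug_abuse_last_year = drug_abuse_last_year,
             obese_last_year = obese_last_year, employed = employed,
             graduated = graduated)
}

small_config <- function(n = 2000L, seed = 101L, ...) {
  scenario_config(n_individuals = as.integer(n), seed = as.integer(seed), ...)
}
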