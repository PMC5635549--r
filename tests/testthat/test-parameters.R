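# Manifest of every published model input (one entry per table row,
# age-banded inputs listed per band). The default registry must contain each
# literal exactly once under its stable identifier.
input_manifest <- rbind(
  data.frame(name = "odds_academic_child", value = 1.35),
  data.frame(name = "odds_obese_child", value = 0.146),
  data.frame(name = "odds_low_self_reg", value = 0.33),
  data.frame(name = "odds_behavior_problems", value = 0.275),
  data.frame(name = "odds_graduate_hs", value = 2.125),
  data.frame(name = "odds_drug_abuse_child", value = 0.13),
  data.frame(name = "odds_diabetes_child", value = 0.001),
  data.frame(name = "odds_judiciary_child", value = 0.099),
  data.frame(name = "or_academic_pc", value = 1.52),
  data.frame(name = "or_academic_behavior", value = 0.229),
  data.frame(name = "or_obese_lsr", value = 3.846),
  data.frame(name = "or_obese_lsr_pc", value = 0.26),
  data.frame(name = "or_obese_nolsr_pc", value = 1.0),
  data.frame(name = "or_behavior_pc", value = 0.59),
  data.frame(name = "or_behavior_lsr", value = 3.8),
  data.frame(name = "or_graduate_academic", value = 1.335),
  data.frame(name = "or_graduate_drug", value = 0.699),
  data.frame(name = "or_graduate_behavior", value = 0.18),
  data.frame(name = "or_drug_behavior", value = 3.8),
  data.frame(name = "or_diabetes_obese_child", value = 5.1),
  data.frame(name = "or_judiciary_drug_child", value = 5.7),
  data.frame(name = "or_judiciary_behavior_child", value = 2.925),
  data.frame(name = "odds_obesity_adult", value = c(0.003, 0.005, -0.002)),
  data.frame(name = "odds_drug_adult", value = 0.007),
  data.frame(name = "odds_diabetes_adult", value = 0.0069),
  data.frame(name = "odds_employment", value = 12.7),
  data.frame(name = "or_diabetes_obese_adult", value = 7.37),
  data.frame(name = "odds_judiciary_adult", value = 0.002),
  data.frame(name = "odds_psych_adult", value = 0.007),
  data.frame(name = "odds_cvd_adult",
             value = c(0.004, 0.007, 0.015, 0.028, 0.052, 0.075)),
  data.frame(name = "or_cvd_diabetes", value = 2.3),
  data.frame(name = "or_cvd_obese", value = 2.3),
  data.frame(name = "or_psych_drug", value = 4.5),
  data.frame(name = "or_judiciary_drug_adult", value = 4.14),
  data.frame(name = "or_judiciary_recidivism", value = 227),
  data.frame(name = "or_employment_graduate", value = 1.88),
  data.frame(name = "or_employment_judiciary", value = 0.029),
  data.frame(name = "or_drug_persistence", value = 47.6),
  data.frame(name = "or_obese_persistence", value = 331),
  data.frame(name = "cost_drug_treatment", value = 1000),
  data.frame(name = "cost_drug_complication", value = 21483),
  data.frame(name = "cost_diabetes_treatment", value = 9975),
  data.frame(name = "cost_diabetes_complication", value = 1575),
  data.frame(name = "cost_obesity_treatment", value = 0),
  data.frame(name = "cost_obesity_complication", value = 732),
  data.frame(name = "cost_incarceration", value = 28893),
  data.frame(name = "cost_unemployment", value = 33160),
  data.frame(name = "cost_pc_annual_per_child", value = 500),
  data.frame(name = "cost_pc_capacity_per_school", value = 100000),
  data.frame(name = "utility_diabetes", value = 0.690),
  data.frame(name = "utility_diabetes_complications", value = 0.350),
  data.frame(name = "utility_drug", value = 0.670),
  data.frame(name = "utility_drug_complications", value = 0.600),
  data.frame(name = "utility_obese", value = 0.710),
  data.frame(name = "utility_obesity_complications", value = 0.500),
  data.frame(name = "utility_prison", value = 0.725)
)

test_that("the default registry carries every published input exactly once", {
  reg <- default_registry()
  expect_gte(nrow(input_manifest), 60)
  for (i in seq_len(nrow(input_manifest))) {
    nm <- input_manifest$name[i]
    v <- input_manifest$value[i]
    hits <- sum(reg$name == nm & reg$value == v)
    expect_identical(hits, 1L,
                     label = sprintf("registry entries for %s = %s", nm, v))
  }
  # no duplicated (name, band) rows
  key <- paste(reg$name, reg$age_lo)
  expect_false(any(duplicated(key)))
})

test_that("spot values and ranges are as published", {
  reg <- default_registry()
  expect_equal(param_value(reg, "odds_graduate_hs"), 2.125)
  expect_equal(param_value(reg, "utility_diabetes_complications"), 0.35)
  row <- reg[reg$name == "or_obese_lsr_pc", ]
  expect_equal(c(row$low, row$high), c(0.08, 0.865))
  expect_equal(param_at_age(reg, "odds_cvd_adult", c(18, 44, 45, 85, 105)),
               c(0.004, 0.004, 0.007, 0.075, 0.075))
  expect_equal(param_at_age(reg, "odds_obesity_adult", c(39, 40, 60)),
               c(0.003, 0.005, -0.002))
  expect_error(param_at_age(reg, "odds_cvd_adult", 10), "outside the bands")
  expect_error(param_value(reg, "odds_cvd_adult"), "age-banded")
})

test_that("override changes a single entry and leaves the original untouched", {
  reg <- default_registry()
  reg2 <- override(reg, "or_behavior_pc", 1.0)
  expect_equal(param_value(reg2, "or_behavior_pc"), 1.0)
  expect_equal(param_value(reg, "or_behavior_pc"), 0.59)
  untouched <- reg$name != "or_behavior_pc"
  expect_equal(reg2$value[untouched], reg$value[untouched])
  # round trip restores the registry
  reg3 <- override(reg2, "or_behavior_pc", 0.59)
  expect_equal(reg3, reg)
  expect_error(override(reg, "nonexistent", 1), "Valid names")
  # banded override: per-band vector or a single band by age
  reg4 <- override(reg, "odds_obesity_adult", c(0.01, 0.01, 0.01))
  expect_equal(param_at_age(reg4, "odds_obesity_adult", c(20, 50, 80)),
               rep(0.01, 3))
  reg5 <- override(reg, "odds_obesity_adult", 0.02, age = 45)
  expect_equal(param_at_age(reg5, "odds_obesity_adult", c(20, 45)),
               c(0.003, 0.02))
  expect_error(override(reg, "odds_obesity_adult", 0.02), "age-banded")
})

test_that("validation reports exactly the known flag on the defaults and catches injected faults", {
  reg <- default_registry()
  v <- validate_registry(reg)
  expect_length(v, 1)
  expect_match(v, "odds_obesity_adult.*-0\\.002")
  expect_length(validate_registry(override(reg, "odds_obesity_adult",
                                           c(0.003, 0.005, 0))), 0)
  bad_util <- override(reg, "utility_prison", 1.2)
  expect_true(any(grepl("utility_prison.*outside \\[0, 1\\]",
                        validate_registry(bad_util))))
  rev_range <- reg
  rev_range$low[rev_range$name == "cost_drug_treatment"] <- 2000
  expect_true(any(grepl("cost_drug_treatment: low exceeds high",
                        validate_registry(rev_range))))
})

test_that("registries round-trip through CSV", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- load_registry(path)
  expect_equal(as.data.frame(back), as.data.frame(reg))
})

test_that("CSV loading enforces completeness and defaults missing ranges", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg[reg$name != "odds_graduate_hs", ], path)
  expect_error(load_registry(path), "odds_graduate_hs")
  reg_na <- reg
  reg_na$low[reg_na$name == "cost_drug_treatment"] <- NA
  reg_na$high[reg_na$name == "cost_drug_treatment"] <- NA
  write_registry(reg_na, path)
  expect_warning(back <- load_registry(path), "\\+/-50%")
  row <- back[back$name == "cost_drug_treatment", ]
  expect_equal(c(row$low, row$high), c(500, 1500))
})

test_that("scenario config files load, apply overrides, and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "scenario:",
    "  n_individuals: 500",
    "  seed: 9",
    "  discount_rate: 0.03",
    "parameter_overrides:",
    "  or_behavior_pc: 1.0",
    "  odds_obesity_adult: [0.004, 0.004, 0.0]"
  ), path)
  loaded <- load_scenario_config(path)
  expect_equal(loaded$config$n_individuals, 500L)
  expect_equal(loaded$config$discount_rate, 0.03)
  expect_equal(param_value(loaded$registry, "or_behavior_pc"), 1.0)
  expect_equal(param_at_age(loaded$registry, "odds_obesity_adult", 70), 0)
  # load_registry() on a config path returns the overridden registry
  expect_equal(load_registry(path), loaded$registry)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario:", "  n_individuals: 10", "typo_section:", "  a: 1"), bad)
  expect_error(load_scenario_config(bad), "typo_section")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario:", "  not_a_knob: 10"), bad2)
  expect_error(load_scenario_config(bad2), "not_a_knob")
})

test_that("scenario invariants are enforced", {
  expect_error(scenario_config(n_individuals = 0), "n_individuals")
  expect_error(scenario_config(discount_rate = 1), "discount_rate")
  expect_error(scenario_config(school_size = 0), "school_size")
  expect_error(scenario_config(capacity_durability = 1), "first 2 years")
})
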