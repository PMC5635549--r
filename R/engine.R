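# Two-arm microsimulation engine. One seed defines one uniform stream per
# arm; uniforms are consumed in a fixed (year, decision-slot, individual)
# order, with every slot drawn for every individual whether or not the draw
# is needed, so the streams of the two arms stay positionally aligned.
# Running both arms from the same seed therefore uses common random numbers:
# a null intervention yields bit-identical trajectories and exactly zero
# deltas, and real deltas are variance-reduced by pairing.

lifetable_from_config <- function(config) {
  if (identical(config$life_table_source, "synthetic")) {
    make_gompertz_lifetable(max_age = config$max_age)
  } else {
    load_life_table(config$life_table_source)
  }
}

.program_cost <- function(config) {
  if (!is.null(config$program_cost_override)) return(config$program_cost_override)
  program_cost_per_student(config$capacity_cost, config$capacity_durability,
                           config$annual_implementation_cost,
                           config$school_size)
}

# Adult phase shared by the engine, the validation analysis and mortality
# calibration: consumes uniforms from the current RNG stream.
run_adult_phase <- function(state, registry, lifetable, acc,
                            discount_rate = 0.05, max_age = 105L,
                            start_t = 13L, cvd_both_mode = "single") {
  n <- nrow(state)
  effective_max <- min(max_age, max(lifetable$age))
  repeat {
    if (!any(state$alive)) break
    age_before <- state$age
    u <- matrix(stats::runif(n * 8L), ncol = 8L)
    state <- .step_year(state, registry, lifetable, u, cvd_both_mode,
                        effective_max)
    surv <- state$alive
    if (any(surv)) {
      s <- state[surv, , drop = FALSE]
      d <- discount_factor(discount_rate, start_t + (age_before[surv] - 18L))
      acc$disc_cost[surv] <- acc$disc_cost[surv] + annual_cost(s, registry) * d
      acc$disc_qaly[surv] <- acc$disc_qaly[surv] + annual_utility(s, registry) * d
      acc$life_years[surv] <- acc$life_years[surv] + 1
    }
  }
  acc
}

#' Simulate an adult cohort from given initial states
#'
#' Runs the annual adult cycle from the supplied states until everyone has
#' died, accruing discounted costs, discounted QALYs and (undiscounted) life
#' years. Useful for validation runs (e.g. the life expectancy of an
#' 18-year-old with obesity) and mortality calibration.
#'
#' @param state Adult state data frame, e.g. from [init_adult_state()].
#' @param registry A `param_registry`.
#' @param lifetable A `life_table`.
#' @param seed Integer seed for the uniform stream.
#' @param discount_rate Annual discount rate.
#' @param max_age Forced-death age.
#' @param start_t Years since model entry at the cohort's current age (13
#'   for age 18 with entry at age 5); affects discounting only.
#' @param cvd_both_mode See [step_adult_year()].
#' @return An `outcome_accumulator` (`life_years` here counts adult years
#'   from the supplied states onward).
#' @export
simulate_adult_cohort <- function(state, registry, lifetable, seed = 1L,
                                  discount_rate = 0.05, max_age = 105L,
                                  start_t = 13L, cvd_both_mode = "single") {
  set.seed(seed)
  run_adult_phase(state, registry, lifetable, new_accumulator(nrow(state)),
                  discount_rate, max_age, start_t, cvd_both_mode)
}

# Full lifetime trajectory of one arm; per-individual outcome vectors.
run_cohort <- function(config, registry, lifetable, arm, seed) {
  set.seed(seed)
  n <- config$n_individuals
  u_child <- matrix(stats::runif(n * 8L), nrow = n, ncol = 8L)
  profile <- draw_child_profile(arm, registry, n = n,
                                pct_low_self_reg = config$pct_low_self_reg,
                                u = u_child,
                                obesity_or_mode = config$obesity_or_mode)
  acc <- new_accumulator(n)
  # Childhood: 13 discounted years at utility 1, no disease costs (health
  # sequelae start in adulthood); optional one-off incarceration charge.
  for (t in 0:12) {
    cost <- if (config$charge_child_judiciary && t == 12L) {
      param_value(registry, "cost_incarceration") * profile$judiciary
    } else {
      rep(0, n)
    }
    acc <- accumulate(acc, cost, rep(1, n), t, config$discount_rate)
  }
  if (arm == "intervention") {
    acc$disc_cost <- acc$disc_cost + .program_cost(config)
  }
  state <- init_adult_state(profile, registry, u = stats::runif(n))
  run_adult_phase(state, registry, lifetable, acc,
                  discount_rate = config$discount_rate,
                  max_age = config$max_age, start_t = 13L,
                  cvd_both_mode = config$cvd_both_mode)
}

.summarise_arm <- function(raw, arm, n) {
  structure(
    list(arm = arm, n = n,
         mean_disc_cost = mean(raw$disc_cost),
         mean_disc_qaly = mean(raw$disc_qaly),
         mean_life_years = mean(raw$life_years),
         se_cost = stats::sd(raw$disc_cost) / sqrt(n),
         se_qaly = stats::sd(raw$disc_qaly) / sqrt(n)),
    class = "arm_result"
  )
}

#' Simulate one arm
#'
#' Runs `n_individuals` lifetime trajectories (childhood phase, then annual
#' adult cycles until death) under the given arm and returns per-arm means
#' with Monte-Carlo standard errors. The intervention arm is charged the
#' per-student program cost once at model entry, undiscounted.
#'
#' @param config A [scenario_config()]; its `arm` field selects the arm.
#' @param registry A `param_registry` (default: built-in).
#' @param lifetable A `life_table` (default: from
#'   `config$life_table_source`).
#' @param seed Master seed (default `config$seed`).
#' @return An `arm_result`: `mean_disc_cost`, `mean_disc_qaly`,
#'   `mean_life_years`, `se_cost`, `se_qaly`, `n`, `arm`.
#' @export
run_arm <- function(config, registry = NULL, lifetable = NULL,
                    seed = config$seed) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(lifetable)) lifetable <- lifetable_from_config(config)
  raw <- run_cohort(config, registry, lifetable, config$arm, seed)
  .summarise_arm(raw, config$arm, config$n_individuals)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm (n = %d)\n", x$arm, x$n))
  cat(sprintf("  discounted cost  $%s (SE %s)\n",
              format(round(x$mean_disc_cost), big.mark = ","),
              format(round(x$se_cost, 1), big.mark = ",")))
  cat(sprintf("  discounted QALYs %.3f (SE %.4f)\n", x$mean_disc_qaly, x$se_qaly))
  cat(sprintf("  life years       %.2f\n", x$mean_life_years))
  invisible(x)
}

#' Compare the intervention and standard arms
#'
#' Runs both arms and returns intervention-minus-standard differences of
#' discounted cost (program cost included; negative means the intervention
#' saves money), discounted QALYs and life years. With `crn = TRUE`
#' (default) both arms consume the identical uniform stream, so the deltas
#' are paired per individual and a null intervention gives exactly zero.
#'
#' @inheritParams run_arm
#' @param crn Use common random numbers across arms (default `TRUE`; when
#'   `FALSE` the intervention arm uses an independent stream).
#' @return A `comparison_result`: `delta_cost`, `delta_qaly`,
#'   `delta_life_years`, their standard errors, both `arm_result`s, `seed`,
#'   `n`, `crn`.
#' @export
compare_arms <- function(config, registry = NULL, lifetable = NULL,
                         seed = config$seed, crn = TRUE) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(lifetable)) lifetable <- lifetable_from_config(config)
  n <- config$n_individuals
  std <- run_cohort(config, registry, lifetable, "standard", seed)
  int <- run_cohort(config, registry, lifetable, "intervention",
                    if (crn) seed else seed + 1L)
  d_cost <- int$disc_cost - std$disc_cost
  d_qaly <- int$disc_qaly - std$disc_qaly
  d_ly <- int$life_years - std$life_years
  se <- function(d) stats::sd(d) / sqrt(n)
  structure(
    list(delta_cost = mean(d_cost), delta_qaly = mean(d_qaly),
         delta_life_years = mean(d_ly),
         se_delta_cost = se(d_cost), se_delta_qaly = se(d_qaly),
         arms = list(standard = .summarise_arm(std, "standard", n),
                     intervention = .summarise_arm(int, "intervention", n)),
         seed = seed, n = n, crn = crn),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Intervention vs standard pre-k (n = %d per arm, seed %d%s)\n",
              x$n, x$seed, if (x$crn) ", common random numbers" else ""))
  cat(sprintf("  delta cost  %s$%s (SE %s) %s\n",
              if (x$delta_cost < 0) "-" else "+",
              format(abs(round(x$delta_cost)), big.mark = ","),
              format(round(x$se_delta_cost, 1), big.mark = ","),
              if (x$delta_cost < 0) "(cost saving)" else ""))
  cat(sprintf("  delta QALYs %+.4f (SE %.4f)\n", x$delta_qaly, x$se_delta_qaly))
  cat(sprintf("  delta life years %+.4f\n", x$delta_life_years))
  invisible(x)
}
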