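# Childhood phase (ages 5-18): a single Markov state with one 13-year cycle.
# The eight binary outcomes are sampled once each, in a fixed topological
# order of the influence diagram, so every event conditions only on events
# already drawn.

.child_events <- c("low_self_reg", "behavior_problems", "academic_proficient",
                   "drug_abuse", "obese", "diabetes", "judiciary", "graduated")

.child_parents <- list(
  behavior_problems   = "low_self_reg",
  academic_proficient = "behavior_problems",
  drug_abuse          = "behavior_problems",
  obese               = "low_self_reg",
  diabetes            = "obese",
  judiciary           = c("drug_abuse", "behavior_problems"),
  graduated           = c("academic_proficient", "drug_abuse", "behavior_problems")
)

#' Adjusted odds of a childhood event
#'
#' Returns the baseline "odds ever" of the event adjusted by exactly the
#' odds ratios applicable given the partial profile: the child's arm, low
#' self-regulation status, and the upstream events of the influence diagram.
#' Vectorised over the rows of `profile`.
#'
#' @param event One of `"behavior_problems"`, `"academic_proficient"`,
#'   `"drug_abuse"`, `"obese"`, `"diabetes"`, `"judiciary"`, `"graduated"`
#'   (low self-regulation is a prevalence draw, not an odds-adjusted event).
#' @param profile Data frame with column `arm` and logical columns for every
#'   upstream event of `event` (no `NA`s among them).
#' @param registry A `param_registry`.
#' @param obesity_or_mode `"multiplicative"` (default) composes the
#'   intervention obesity OR 0.26 with the low-self-regulation OR 3.846;
#'   `"substitute"` replaces it.
#' @return Nonnegative odds, one per profile row.
#' @export
child_event_odds <- function(event, profile, registry,
                             obesity_or_mode = c("multiplicative", "substitute")) {
  obesity_or_mode <- match.arg(obesity_or_mode)
  if (!event %in% names(.child_parents)) {
    stop("unknown childhood event '", event, "'; expected one of: ",
         paste(names(.child_parents), collapse = ", "))
  }
  if (is.null(profile$arm)) stop("profile must carry an `arm` column")
  for (f in .child_parents[[event]]) {
    if (is.null(profile[[f]]) || anyNA(profile[[f]])) {
      stop("upstream event '", f, "' is unset; sample events in dependency order")
    }
  }
  pc <- profile$arm == "intervention"
  pv <- function(nm) param_value(registry, nm)
  switch(event,
    behavior_problems = pv("odds_behavior_problems") *
      ifelse(profile$low_self_reg, pv("or_behavior_lsr"), 1) *
      ifelse(pc, pv("or_behavior_pc"), 1),
    academic_proficient = pv("odds_academic_child") *
      ifelse(pc, pv("or_academic_pc"), 1) *
      ifelse(profile$behavior_problems, pv("or_academic_behavior"), 1),
    drug_abuse = pv("odds_drug_abuse_child") *
      ifelse(profile$behavior_problems, pv("or_drug_behavior"), 1),
    obese = {
      base <- pv("odds_obese_child")
      if (obesity_or_mode == "substitute") {
        # 0.26 already encodes the trial contrast within the subgroup
        ifelse(profile$low_self_reg,
               base * ifelse(pc, pv("or_obese_lsr_pc"), pv("or_obese_lsr")),
               base * ifelse(pc, pv("or_obese_nolsr_pc"), 1))
      } else {
        base * ifelse(profile$low_self_reg, pv("or_obese_lsr"), 1) *
          ifelse(pc,
                 ifelse(profile$low_self_reg, pv("or_obese_lsr_pc"),
                        pv("or_obese_nolsr_pc")),
                 1)
      }
    },
    diabetes = pv("odds_diabetes_child") *
      ifelse(profile$obese, pv("or_diabetes_obese_child"), 1),
    judiciary = pv("odds_judiciary_child") *
      ifelse(profile$drug_abuse, pv("or_judiciary_drug_child"), 1) *
      ifelse(profile$behavior_problems, pv("or_judiciary_behavior_child"), 1),
    graduated = pv("odds_graduate_hs") *
      ifelse(profile$academic_proficient, pv("or_graduate_academic"), 1) *
      ifelse(profile$drug_abuse, pv("or_graduate_drug"), 1) *
      ifelse(profile$behavior_problems, pv("or_graduate_behavior"), 1)
  )
}

#' Sample complete childhood profiles
#'
#' Draws the eight childhood outcomes for `n` children as Bernoulli events
#' in the fixed order low self-regulation, behavior problems, academic
#' proficiency, drug abuse, obesity, diabetes, judiciary interaction,
#' graduation: low self-regulation from its prevalence, every other event
#' from [child_event_odds()] converted via [odds_to_prob()].
#'
#' @param arm `"standard"` or `"intervention"`.
#' @param registry A `param_registry`.
#' @param n Number of children.
#' @param pct_low_self_reg Prevalence of low self-regulation at pre-k entry.
#' @param u Optional `n x 8` matrix of uniforms (one column per event in
#'   sampling order) for common-random-number designs; drawn from the
#'   current RNG stream when `NULL`.
#' @param obesity_or_mode Passed to [child_event_odds()].
#' @return Data frame with column `arm` and one logical column per event; no
#'   field is left unset.
#' @export
draw_child_profile <- function(arm, registry, n = 1L, pct_low_self_reg = 0.25,
                               u = NULL,
                               obesity_or_mode = c("multiplicative", "substitute")) {
  arm <- match.arg(arm, c("standard", "intervention"))
  obesity_or_mode <- match.arg(obesity_or_mode)
  if (is.null(u)) {
    u <- matrix(stats::runif(n * 8L), nrow = n, ncol = 8L)
  }
  stopifnot(nrow(u) == n, ncol(u) == 8L)
  profile <- data.frame(arm = rep(arm, n))
  profile$low_self_reg <- u[, 1L] < pct_low_self_reg
  for (k in 2:8) {
    ev <- .child_events[k]
    odds <- child_event_odds(ev, profile, registry, obesity_or_mode)
    profile[[ev]] <- u[, k] < odds_to_prob(odds)
  }
  profile
}
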