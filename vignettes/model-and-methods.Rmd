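---
title: "Model structure, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prekCEA)
```

# What the model is

`prekCEA` is a two-arm microsimulation of the lifetime consequences of a
family-centered enhancement to pre-kindergarten programming (ParentCorps)
versus standard pre-k, for children entering pre-k in high-poverty urban
schools. Each simulated individual enters at age 5, passes through a
one-shot **childhood phase** (a single Markov state with one 13-year
cycle), and then through an **adult phase** of annual cycles until death.
Outcomes are discounted societal costs (2015 $US), discounted
quality-adjusted life years (QALYs), and undiscounted life years;
arm-level results are means over 100,000 individuals in the base case.

## Childhood phase

Eight correlated binary outcomes are sampled once each, in a fixed
topological order of the influence diagram, so every event conditions only
on events already drawn:

1. low self-regulation (prevalence draw; base 25%),
2. behavior problems,
3. academic proficiency,
4. drug abuse,
5. obesity,
6. diabetes,
7. judiciary interaction,
8. high-school graduation.

Each event's probability comes from a baseline "odds ever" adjusted
multiplicatively by the odds ratios of its diagram parents (and, in the
intervention arm, by the intervention effect ORs: 0.59 for behavior
problems, 1.52 for academic proficiency, and 0.26 for obesity within the
low-self-regulation subgroup), then converted with
`probability = odds/(1 + odds)`. Any topological order of the diagram
gives the same joint distribution because each event conditions only on
its parents; one order is fixed for reproducibility.

Childhood accrues 13 discounted life years at utility 1 in both arms and
no disease costs (health sequelae are assumed to begin in adulthood).
Because the childhood contribution is identical across arms it cancels in
every delta. A switch (`charge_child_judiciary`, default off) charges one
discounted year of incarceration cost at childhood year 12 for children
with a judiciary interaction; the published description is silent on this,
and year 12 is chosen because such interactions cluster in adolescence.

### The obesity subgroup OR

The intervention obesity OR (0.26) was estimated as an
intervention-vs-control contrast *within* the low-self-regulation
subgroup. The default therefore composes it with the subgroup risk OR
(0.146 × 3.846 × 0.26); `obesity_or_mode = "substitute"` instead replaces
the subgroup OR (0.146 × 0.26), for users who read the table's
conditional-on-subgroup phrasing as an absolute subgroup odds adjustment.

## Adult phase

The adult state tracks five attributes — obesity, diabetes, drug abuse,
judiciary interaction, employment — plus two absorbing sequela flags
(cardiovascular disease for obesity/diabetes, psychiatric disorder for
drug abuse), one-year memory flags, graduation status, age, and vital
status. Within each year the updates apply in a fixed order:

1. **death** — background `qx(age)` times the product of the excess
   multipliers of active conditions (cvd 2.0, diabetes 1.5, drug 1.5 by
   default), capped at 1;
2. **obesity** — age-banded incidence odds (0.003 / 0.005 / −0.002),
   multiplied by the persistence OR 331 if obese last year; the negative
   over-60 value is implemented as zero incidence plus an annual remission
   probability of 0.002, the only reading that keeps probabilities valid;
3. **diabetes** (absorbing) — odds 0.0069, × 7.37 given this year's
   obesity;
4. **drug abuse** — odds 0.007, × 47.6 if abusing last year;
5. **cardiovascular disease** (absorbing) — age-banded odds
   (0.004 … 0.075), × 2.3 given diabetes or obesity. With both conditions
   a single factor of 2.3 is applied (the published assumption is that the
   two carry the same cardiovascular risk); `cvd_both_mode =
   "multiplicative"` squares it instead;
6. **psychiatric disorder** (absorbing) — odds 0.007, × 4.5 given this
   year's drug abuse;
7. **judiciary interaction** — odds 0.002, × 4.14 given drug abuse,
   × 227 given an interaction last year;
8. **employment** — fixed for life, except re-drawn with OR 0.029 in the
   year after a judiciary interaction.

Death comes first so decedents accrue no cost or utility in their final
year; transitions later in the order condition on statuses already updated
this year (so diabetes risk reflects current obesity), while persistence
and recidivism ORs condition on last year's statuses. The published model
summarises this state space as "32 Markov states"; here the attributes are
tracked directly per individual and the state count is emergent
bookkeeping.

At the childhood-adult handoff, disease statuses carry over and the
obesity/drug memory flags are seeded with them, so persistence ORs apply
from the first adult year. The judiciary memory starts clear: a childhood
interaction happened somewhere in a 13-year window, not necessarily the
prior year, and the recidivism OR comes from within-three-years-of-release
data. Graduation's only adult effect is on the initial employment draw
(OR 1.88 on odds 12.7); effects of graduation on adult judiciary risk and
of health on employment are deliberately out of scope, matching the
published assumptions.

## Costs and utilities

Costs are additive over active conditions: treatment costs (drug $1000,
diabetes $9975, obesity $0 per year), complication costs attached to the
sequela flags (psychiatric $21,483; cardiovascular $1575 when diabetic,
$732 otherwise — diabetes takes precedence because the complication
schedule is disease-specific while the flag is shared), incarceration
$28,893 in an interaction year, and the unemployment opportunity cost
$33,160 in any year not employed. Utilities follow the minimum rule over
active conditions (obesity 0.71, diabetes 0.69, drug 0.67, psychiatric
sequela 0.60, cardiovascular sequela 0.35 with diabetes / 0.50 without,
prison 0.725, the latter in the interaction year only); unemployment never
reduces utility, because its cost is already counted. Everything is
discounted at 5%/yr from model entry at age 5; the alternative of
discounting from age 18 would scale all adult quantities by 1.05^13 ≈ 1.9
but cancels nowhere, so entry-anchored discounting is used throughout.
The intervention arm is charged the amortized per-student program cost —
`(200{,}000 + 3 × 40{,}000)/(72 × 5) = $888.89` in the base case — once at
entry, undiscounted.

# Background mortality and the synthetic life table

The adult death draw uses an age-indexed life table (`age`, `qx` CSV).
Because the national table the original analysis used cannot be bundled,
the package ships a deterministic synthetic Gompertz generator:
`qx = 1 − exp(−a·e^{b·age})` with defaults `a = 1e-4`, `b = 0.085`,
closing at age 105. Those defaults give a life expectancy at birth of
72.7 years and at 18 of 54.9 years — the monotone-increasing adult hazard
and overall scale of a contemporary US period table, without its
infant-mortality hook, accident hump, or old-age plateau. Consequences:
simulated absolute life expectancies (and anything dollar-weighted by
years lived) are a few years short of CDC-2008-based values, so passing
tests against the synthetic table demonstrate internal consistency and
direction of effects, not the published absolute magnitudes. Supplying a
real table via `life_table_source` restores the intended calibration.

`life_expectancy()` counts completed years
(`sum over t of prod(1 - qx)`), matching the simulation's year-granular
accounting; the half-cycle correction is available behind a flag but off
by default, as the published description never mentions one.

The disease-specific excess-mortality multipliers are not published.
`calibrate_mortality_multipliers()` rescales their excess over 1 by a
common factor until the simulated remaining life expectancy of an
18-year-old with obesity hits a target (60.1 years against the intended
national table). Against the synthetic table that target is unreachable —
the synthetic baseline at 18 is already below it — and the function
reports a bracketing error rather than extrapolating; the stated defaults
(2.0/1.5/1.5) are retained as base values.

# Randomness and common random numbers

One master seed defines one uniform stream per arm. Uniforms are consumed
in a fixed (year, decision-slot, individual) order, and every slot is
drawn for every individual whether or not the decision applies, so the
streams of the two arms stay positionally aligned as trajectories diverge.
Running both arms from the same seed therefore gives common random
numbers: a null intervention (all effect ORs at 1, program cost 0) yields
bit-identical trajectories and exactly zero deltas, and real deltas are
paired per individual, which cuts their Monte-Carlo error by roughly an
order of magnitude at base-case effect sizes. The cost of this design is
that results are tied to the cohort being simulated in one block (no
per-individual substreams, no parallel batching); within one R session the
same seed always reproduces the same trajectories.

# Sensitivity and threshold machinery

`one_way_sa()` pushes each parameter to its lower and upper plausible
bound (each band of an age-banded parameter to its own bound), reruns the
paired comparison at the base seed, and records both outcomes — ready for
a tornado diagram. Parameters published without a range (program costs,
utilities, the obesity persistence OR) are fixed by construction and
produce zero-width bars if requested.

`threshold_search()` bisects the common-random-number estimate of the
criterion (net cost delta by default) to 10^-3 of the bracket width; with
a fixed seed the estimate is a deterministic function of the parameter, so
bisection is well defined despite Monte-Carlo noise, and for the
per-student price the identity `net = gross + price` makes the threshold
equal the gross savings exactly. `break_even_school_size()` exploits the
same structure: enrollment only changes the per-student charge, so one
program-cost-free run prices every enrollment.

# Problem sizes and tolerances

Defaults and test scales, chosen as the package's own desk-scale
conventions: base-case comparisons at n = 50,000 (SE of the cost delta
≈ $66 under pairing); disease-free life-table consistency at n = 100,000
against the deterministic expectation within 3 Monte-Carlo SE; one-year
transition calibration at 10^6 single steps per prototype state, against
exact mixture probabilities that account for within-year status updates;
tornado sweeps at n = 10,000 per run. Stochastic checks use 3-SE bands
throughout; exact checks (costing arithmetic, odds conversions,
common-random-number null equivalence) are asserted bit-exactly.

# Known limitations

* The adult persistence ORs are applied literally as published
  (odds × OR, then conversion). For obesity, 0.003 × 331 gives odds 0.993,
  i.e. a *probability* of staying obese of only ≈ 0.50/yr, although the
  same published table note back-calculates 331 from "odds 0.007 of
  non-persistence" (persistence probability ≈ 0.993). The two published
  statements are mutually inconsistent; this package follows the stated
  adjustment rule. The consequence is that childhood obesity and drug
  advantages decay within a few adult years, the obesity→diabetes savings
  channel is small, and desk-scale cost deltas are roughly break-even
  rather than clearly cost saving — the headline savings reported for the
  original model would require the ≈ 0.993 persistence reading.
* The synthetic life table reproduces shape, not the national level;
  absolute life expectancies run a few years short (see above).
* Childhood has no internal dynamics (one 13-year cycle), no service
  costs, and no mortality; adult drug-abuse incidence does not depend on
  childhood drug abuse beyond the carried status plus persistence OR.
* No probabilistic sensitivity analysis: parameters are varied one-way,
  multi-way via scenario knobs, and by threshold search only, mirroring
  the published analysis plan.
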