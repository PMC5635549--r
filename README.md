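# prekCEA

Lifetime cost-effectiveness microsimulation of a family-centered
pre-kindergarten enhancement (ParentCorps) versus standard pre-k, for
children entering pre-k in high-poverty urban schools — written for health
economists and prevention researchers who want the published decision
model as tested, re-runnable code.

Each simulated child enters at age 5 and passes through a one-shot
childhood phase (a single Markov state, one 13-year cycle) in which eight
correlated binary outcomes are drawn — low self-regulation, behavior
problems, academic proficiency, drug abuse, obesity, diabetes, judiciary
interaction, high-school graduation — each from baseline odds adjusted
multiplicatively by the odds ratios of its influence-diagram parents and
converted by `p = odds/(1 + odds)`. Adults then move through annual Markov
cycles over five attributes (obesity, diabetes, drug abuse, judiciary
interaction, employment) and two absorbing sequelae (cardiovascular
disease, psychiatric disorder), with age-banded incidence, persistence and
recidivism odds ratios, and background mortality from an age-indexed life
table scaled by disease-specific hazard multipliers. Outcomes are
discounted societal costs (2015 $US, 5%/yr), discounted QALYs under the
minimum-utility rule, and life years:

```
ΔC = E[C_int − C_std] + program cost/student,   ΔE = E[QALY_int − QALY_std]
```

estimated with common random numbers (both arms consume the identical
uniform stream, so a null intervention yields exactly zero deltas). A
one-way sensitivity (tornado) engine, threshold bisection, break-even
enrollment search, and a mortality-calibration helper sit on top.

## Worked example

```r
library(prekCEA)

cfg <- scenario_config(n_individuals = 50000L, seed = 20251L)
compare_arms(cfg)
#> Intervention vs standard pre-k (n = 50000 per arm, seed 20251, common random numbers)
#>   delta cost  +$33 (SE 66.2)
#>   delta QALYs +0.0158 (SE 0.0008)
#>   delta life years +0.0130

program_cost_per_student(200000, 5, 40000, 72)
#> [1] 888.8889
```

Read: at a program price of $888.89 per student, the intervention arm
gains 0.0158 discounted QALYs per child and its net discounted cost
difference is +$33 ± $66 — gross savings of $856 per child against the
synthetic life table, statistically indistinguishable from the program
price. The QALY gain is unambiguous; the absolute dollar magnitudes
depend on the life table and on the literal persistence-odds-ratio
arithmetic, as discussed in the methods vignette
(`vignettes/model-and-methods.Rmd`).

The numbered drivers under `analysis/` run the full workflow and write
tables to `results/`: `01_base_case.R` (paired comparison and gross
savings), `02_validation.R` (life-table consistency and the obese-18-
year-old life expectancy), `03_tornado.R` (one-way sensitivity sweep),
`04_thresholds.R` (per-student price threshold and break-even school
size).

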