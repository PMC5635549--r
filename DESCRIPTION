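Package: prekCEA
Title: Lifetime Cost-Effectiveness Microsimulation of a Family-Centered
    Pre-Kindergarten Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-arm Markov state-transition microsimulation of the lifetime
    costs and quality-adjusted life years (QALYs) of a family-centered
    enhancement to pre-kindergarten programming, compared with standard
    pre-k, from a societal cost perspective. A one-shot childhood phase
    (ages 5-18) samples eight correlated binary outcomes (low
    self-regulation, behavior problems, academic proficiency, drug abuse,
    obesity, diabetes, judiciary interaction, high-school graduation); an
    annual-cycle adult phase evolves five attributes and their health
    sequelae until death against an age-indexed background life table.
    Includes a validated registry of all model inputs with plausible
    ranges, odds/odds-ratio risk algebra with DerSimonian-Laird pooling,
    discounted cost and QALY accounting, intervention costing, common
    random numbers across arms, one-way (tornado) sensitivity analysis,
    and threshold search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
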