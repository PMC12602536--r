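Package: obemod
Title: Markov Cohort Cost-Effectiveness Model for Obesity Pharmacotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A BMI-driven Markov state-transition cohort model for the
    economic evaluation of weight-management pharmacotherapy (semaglutide
    2.4 mg versus liraglutide 3.0 mg) from a third-party payer perspective.
    Implements a 65-state comorbidity state space (none, single, double and
    triple combinations of seven obesity-related complications, plus death),
    per-cycle BMI trajectories with a 12-week non-responder stopping rule and
    post-treatment catch-up, BMI-linked incidence and mortality adjustment,
    half-cycle-corrected discounted accumulation of costs, life-years and
    QALYs, and the full decision-analytic toolkit: ICER/NMB/cost-effectiveness
    plane, one-way deterministic sensitivity analysis with tornado ranking,
    scenario batteries, and probabilistic sensitivity analysis with
    Beta/Gamma/Lognormal parameter draws, CEAC and quadrant shares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
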