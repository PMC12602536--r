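# obemod

A Markov cohort cost-effectiveness model for obesity pharmacotherapy:
semaglutide 2.4 mg versus liraglutide 3.0 mg from a third-party payer
perspective, for health economists and HTA analysts who need a transparent,
fully configurable, testable re-implementation of a BMI-driven
state-transition evaluation.

## The model

A hypothetical adult cohort (mean age 48.6, BMI 41.5 kg/m², 73.6% female)
enters a 65-state Markov model — the no-complication state, all single, pair
and triple combinations of seven obesity-related complications (T2D, ACS,
hypertension, dyslipidemia, asthma, CKD, sleep apnea), and absorbing death —
and is followed for 40 years with quarterly cycles in year one, annual
cycles thereafter, half-cycle correction, and 3.5%/year discounting of costs
and outcomes.

BMI is the sole surrogate risk factor. Each arm's %-weight-change timeline
(with a 12-week non-responder stopping rule at ≥ 5% weight loss;
non-responder rates 24.6% / 38.6%) drives per-cycle BMI, which maps to
complication incidence through calibrated log-linear risk functions

    p_annual(BMI) = min(1, p0 · exp(β·(BMI − BMI_ref)) · Π covariate multipliers)

and to mortality through BMI-band hazard ratios on residual (cause-deducted)
all-cause mortality plus per-condition excess-mortality multipliers. After
treatment stops (maximum 2 years), effects decay linearly over a 3-year
catch-up until the path rejoins natural progression (+0.47 kg/year).
Utilities combine a published baseline regression (cubic in BMI) with
additive condition disutilities and one-time event disutilities; costs
combine titration-aware payer drug costs (statutory 25% co-payment),
universal monitoring, condition state costs and acute-event tariffs, all in
2025 €. Decision metrics are the ICER (ΔC/ΔQ), net monetary benefit
(λ·ΔQ − ΔC), tornado-ranked one-way sensitivity, a ten-scenario battery, and
a 1,000-iteration probabilistic sensitivity analysis with Beta/Gamma/
Lognormal draws, CE-plane quadrant shares and the CEAC.

Arm-level efficacy timelines, adverse-event rates, risk calibrations, the
life table and mortality adjustments ship as clearly tagged synthetic
fixtures (the primary inputs live in non-redistributable supplementary
material); every number in the configuration carries a `[PAPER]`/`[FIXTURE]`
provenance tag — see `config_provenance()` and the methods vignette.

## Worked example

```r
library(obemod)

cfg <- default_config()          # packaged base case (also inst/extdata/base_case.yaml)
run <- run_comparison(cfg)       # semaglutide vs liraglutide
run$comparison
#> <obemod_comparison>
#>   incremental cost:     1734.32 EUR
#>     monitoring        5.53
#>     state          -616.06
#>     treatment      2339.41
#>     event             5.43
#>   incremental QALYs:     0.0897   incremental LYs: 0.0443
#>   ICER: 19324 EUR/QALY (NE quadrant)
#>   NMB wtp_27117: 699 EUR
#>   NMB wtp_30000: 958 EUR
#>   NMB wtp_34000: 1317 EUR
```

Under the fixture calibrations, semaglutide adds 0.0897 discounted QALYs and
0.044 discounted life-years at €1,734 higher lifetime cost — higher drug
acquisition spend partly offset by €616 lower complication state costs —
giving an ICER of €19,324/QALY, below all three configured willingness-to-pay
thresholds (positive NMB at €27,117, €30,000 and €34,000 per QALY).

Scenario, one-way and probabilistic analyses:

```r
run_scenarios(cfg)                        # ten structural scenarios + base
run_dsa(cfg, top = 11)                    # tornado-ranked one-way sensitivity
psa <- run_psa(cfg, n = 1000, seed = 1)   # probabilistic analysis
quadrant_shares(psa$draws)                # CE-plane shares
ceac(psa$draws)                           # acceptability curve
```

Scenario overrides are plain path/value pairs (packaged YAML copies in
`inst/extdata/scenarios/`):

```r
sc <- apply_scenario(cfg, scenario_specs()$weight_back_in_1_year)
run_comparison(sc)$comparison$icer_qaly$value
```

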