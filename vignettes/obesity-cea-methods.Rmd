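---
title: "Methods: a BMI-driven Markov cohort model for obesity pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a BMI-driven Markov cohort model for obesity pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

obemod implements a cohort state-transition (Markov) model for the economic
evaluation of weight-management pharmacotherapy — semaglutide 2.4 mg versus
liraglutide 3.0 mg — from a third-party payer perspective. This vignette is
the package's own account of the model: its structure, assumptions, tunable
parameters, numerical conventions, and limitations. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## Model structure

The cohort is followed over a 40-year horizon through a state space of 65
health states: the *no-complication* state, every single, pair and triple
combination of seven obesity-related complications — type 2 diabetes (T2D),
acute coronary syndrome (ACS), hypertension, dyslipidemia, asthma, chronic
kidney disease (CKD) and obstructive sleep apnea (OSA) — and an absorbing
death state. Complications are acquired, never remitted; at most one
condition can be added per cycle, and states already carrying three
conditions acquire nothing further. Cycles are quarterly in the first model
year (to resolve the 12-week treatment-response assessment and early
discontinuation) and annual thereafter; a final partial cycle is appended
when a sensitivity analysis sets a non-integer horizon.

Costs and health outcomes are accumulated with a half-cycle correction —
each cycle's reward rate is valued at the average of start- and end-of-cycle
occupancy — and discounted at 3.5%/year for both costs and outcomes, the
rate used in the local evaluation literature. Discounting is applied at the
mid-cycle time (start + length/2), which pairs naturally with half-cycle
rewards; a `model.discount_timing = "start"` flag switches to start-of-cycle
discounting for sensitivity work. Results are expressed as discounted
costs (2025 €), life-years (LYs), quality-adjusted life-years (QALYs), and
the incremental cost-effectiveness ratio

$$\mathrm{ICER} = \frac{\Delta C}{\Delta Q},$$

assessed against willingness-to-pay thresholds of €27,117, €30,000 and
€34,000 per QALY (all three circulate in the Greek threshold literature, so
the configuration carries them as a list).

## BMI trajectories

BMI is the sole surrogate risk factor: treatment affects BMI, and BMI drives
complication incidence, excess mortality and (through the utility
regression) quality of life. Each arm's trajectory is assembled from
%-weight-change anchors at trial assessment weeks, linearly interpolated and
held at the last anchor (plateau) beyond it. Percentages rather than
absolute kilograms are used so the same timeline scales to any baseline BMI.

The cohort is split at the 12-week assessment into responders (≥ 5% weight
loss, inclusive at the boundary) and non-responders, at the published rates
of 24.6% (semaglutide) and 38.6% (liraglutide). Non-responders stop drug
therapy and follow the diet-and-exercise trajectory from week 12 onwards.
Responders continue for at most 2 years (base case); during treatment an
adverse-event discontinuation hazard (annual probability, a fixture value)
routes a small fraction to early discontinuation, resolved at cycle
boundaries after week 12 — a discretization chosen because the cohort
engine advances occupancy per cycle anyway.

After any stop, the residual effect decays linearly over
`model.catch_up_years` (base 3; scenario value 1) from the BMI at stop to
the counterfactual trajectory, after which the path *is* the counterfactual.
Two design choices matter here:

* **Common reference path.** The natural-progression reference
  $N(t) = \mathrm{BMI}_0 + (0.47\,\mathrm{kg/y}/h^2)\,t$ starts its drift at
  model entry rather than at each pathway's individual return-to-baseline
  moment. This gives every pathway one common counterfactual, so all arms
  converge *exactly* (to numerical precision) once catch-up completes — the
  model's "effects are transient" contract, verified as a test invariant.
  The cost of this simplification is that drift accrues during the treated
  years too: about 0.16 BMI units over a 2-year treatment course, second
  order relative to treatment effects of 3–7 BMI units.
* **Units of drift.** The 0.47 value is a *weight* rate (kg/year) converted
  to BMI units through height squared. Some models apply such rates directly
  in BMI units; `model.weight_gain_units = "bmi"` supports that reading.

The diet-and-exercise arm is lifestyle-only: the maximum pharmacotherapy
duration and adverse-event machinery do not apply to it; it follows its own
timeline and then rejoins $N(t)$ via the same catch-up rule. The scenario
battery includes reversion to natural progression *without* residual
lifestyle benefit (`model.post_treatment_pathway = "natural"`).

## From BMI to transition probabilities

The published evaluations in this area feed BMI into large published risk
equations (QDiabetes, QRISK3, Framingham recurrent-CHD, and cohort-study
incidences). Those coefficient sets are deliberately **not** re-implemented
here: the model exposes a calibrated log-linear interface per condition,

$$p_{\text{annual}}(\mathrm{BMI}) = \min\!\left(1,\; p_0 \,
  e^{\beta\,(\mathrm{BMI} - \mathrm{BMI}_{\mathrm{ref}})} \prod_k
  \big(1 + x_k (m_k - 1)\big)\right),$$

with $p_0$ the annual incidence at the reference BMI, $\beta$ the log
relative risk per BMI unit, and covariate multipliers $m_k$ applied at
cohort prevalence $x_k$. Any calibrated function — including a full
published equation — can be dropped in through the configuration. The
shipped calibrations are synthetic fixtures at plausible epidemiological
magnitudes (e.g. annual T2D incidence ~0.6% at BMI 30 with RR ≈ 1.09 per
BMI unit and a prediabetes multiplier), tagged `[FIXTURE]` in the
provenance log; no acceptance check depends on their specific values.

Annual probabilities are converted to cycle probabilities by constant-hazard
compounding, $1-(1-p)^{\ell}$ for cycle length $\ell$, so four quarterly
cycles reproduce the annual probability exactly. Within a cycle, competing
acquisitions are normalized: the joint-acquisition mass
$1-\prod_c(1-p_c)$ is redistributed proportionally over single
acquisitions, keeping matrices row-stochastic while forbidding
multi-condition jumps. At quarterly/annual granularity with incidences of a
few percent the correction is tiny. A true joint-acquisition rule is not
implemented (the configuration flag is validated off), since it would
require multi-add transitions the state space does not index.

## Mortality

All-cause mortality comes from a parametric Gompertz–Makeham life table
(annual hazard $A + B_{\text{sex}} e^{\theta\,\mathrm{age}}$), a
download-free stand-in for a national life-table extract, with lookup at
`floor(age)` and a hard error outside 18–110 (no extrapolation). To avoid
double counting, deaths attributable to the modeled diseases are deducted
proportionally (cause fractions summing to 0.35 in the fixtures), and the
residual is scaled by BMI-band hazard ratios (5-unit bands, HR fixed at 1
for the 18.5–25 reference band). Disease mortality is then reintroduced
state-specifically through per-condition excess-hazard multipliers applied
multiplicatively on the probability scale and capped at 1. Proportional
deduction rather than cause-deleted life-table algebra is used; at these
magnitudes the difference is second order.

## Utilities

The complication-free utility is the published regression
(intercept 0.942975, with age, cardiovascular history, hypertension,
smoking, prediabetes, and linear/quadratic/cubic BMI terms), evaluated at
cohort-mean covariates and clamped to [0, 1]. Two modes exist because the
regression evaluated at the cohort's baseline means does **not** reproduce
the separately published summary baseline utility of 0.78 (SE 0.023) — the
raw polynomial gives ≈ 0.88 at those means, a documented inconsistency in
the source material that the package exposes rather than hides:

* `"fixed"` (default): utility is anchored at 0.78 at baseline and moves
  with the regression's BMI/age gradient,
  $u(t) = 0.78 + f(\mathrm{BMI}_t, \mathrm{age}_t) - f(\mathrm{BMI}_0,
  \mathrm{age}_0)$. This keeps the published level while preserving dynamic
  response to the BMI trajectory.
* `"regression"`: the raw polynomial value.

Condition disutilities (e.g. T2D −0.029, CKD −0.049) are additive on the
baseline, clamped to [0, 1]; acute-event disutilities (ACS −0.129, stroke
−0.181, …) are one-time decrements applied in the cycle of occurrence, not
duration-weighted. On-treatment adverse events (major gastrointestinal
events, hypoglycaemia) apply only while on drug, scaled by the on-treatment
cohort fraction. The minor/major hypoglycaemia cost pair is mapped to the
non-severe/severe disutility pair respectively.

## Costs

All costs are 2025 euros from the payer perspective; indirect costs are out
of scope. Conventions:

* **Monitoring** (€124.88/year) is universal across alive states; the
  no-complication state therefore costs exactly the monitoring tariff, and
  condition state costs (e.g. T2D €1,125.91/year) are additive on top. A
  `costs.noncomplication_extra` field supports the alternative reading where
  monitoring attaches only to the no-complication state.
* **Drug acquisition**: the payer pays `payer_share` (0.75, the statutory
  25% co-payment) of listed prices. Dose-specific pack prices follow a
  titration calendar (semaglutide: 4 weeks each at 0.25/0.5/1.0/1.7 mg,
  then 2.4 mg maintenance; liraglutide: flat price). Pack coverage days are
  a configuration field because pack sizes are not stated alongside the
  listed prices; the default reads a listed price as one pen ≈ one week's
  supply (`pack_days = 7`), the reading consistent with the published
  arm-level annual acquisition cost scale. A 28-day-supply reading is one
  configuration change away. Per-cycle drug cost integrates the
  piecewise-constant price calendar against the on-treatment fraction
  exactly (titration boundaries, the week-12 assessment and the treatment
  stop all split the integral), which is why it matches a day-by-day
  calendar-walk oracle in the tests.
* **Consumables** (needle tariff, €33.58/year while on treatment) are
  booked at full tariff without the drug co-payment split.
* **Acute events**: new ACS acquisitions (transition flux into ACS-bearing
  states) are priced as a myocardial-infarction/angina mix with a fatal/
  non-fatal tariff split; stroke and TIA enter as BMI-linked per-person-year
  event rates.

## Sensitivity machinery

**One-way (tornado).** Each item is varied to ±25% of base (the
conservative convention when no empirical interval is published), the full
two-arm model is rerun at each bound, and items are ranked by absolute ICER
span; the top 11 are reported (configurable), mirroring the usual tornado
presentation.

**Scenarios.** The packaged battery covers disease-specific-mortality-only,
treatment durations of 3–9 years, the trial-product estimand with and
without the stopping rule (stopping-rule removal keeps the whole cohort on
treatment, which raises drug cost), post-treatment reversion without
lifestyle benefit, and 1-year accelerated regain.

**Probabilistic.** 1,000 Monte Carlo iterations; each iteration redraws
every sampled parameter independently and reruns both arms. Distribution
assignment follows standard practice: Gamma for costs, Beta for
probabilities and utility quantities (disutilities sampled on their
magnitude and negated), and Lognormal — chosen over Normal for positivity —
for multiplicative effects. Treatment efficacy is perturbed by a single
arm-level multiplier scaling the whole %-weight-change timeline, preserving
its shape, because anchor-level sampling is not identified by the available
information. Where no standard error is published the default rule
`se = 0.2 × point estimate` applies; the published utility SEs are used
where available. Regulated drug tariffs are treated as certain. Parameters
are drawn without correlation — a stated limitation, since correlated
sampling could shift mean PSA results relative to the deterministic run.
Out-of-range draws are clamped to their valid domain and counted per
iteration. The CEAC is evaluated on a λ-grid from 0 to 50,000 in steps of
500, always including 9,000, 27,117, 30,000 and 34,000.

## Numerical choices and degenerate inputs

* Competing-risk normalizer `(1 - prod(1-p))/sum(p)` with a zero-sum guard.
* `mm_beta`/`mm_gamma`/`mm_lognormal` method-of-moments fits with a
  point-mass guard below `se = 1e-12` (the degenerate-PSA validation limit)
  and a hard error when `se^2 ≥ mean(1-mean)` for the Beta.
* Utilities clamped to [0, 1] after every composition; transition rows
  checked to sum to 1 within 1e-9; occupancy conservation verified per
  cycle.
* The 12-week assessment aligns with the first quarterly cycle boundary
  (week 13); the ≤ 1-week offset is accepted by design.
* Ages advance by cycle length; life-table lookup uses `floor(age)`.

## What the fixtures do and do not emulate

The synthetic fixture set (`make_default_fixtures()`) supplies what the
non-redistributable supplementary material withholds: efficacy timelines
patterned on GLP-1 dose-escalation topline magnitudes, adverse-event rates,
risk calibrations, the parametric life table, BMI hazard-ratio bands and
excess-mortality multipliers. It preserves the *structure* of real inputs
(ordering of arm efficacy, age-monotone mortality, plausible incidence
scales) but not their exact values. Consequently, green tests demonstrate
that the machinery is correct — arithmetic identities, oracle equivalence,
invariants, directional effects — not that the shipped numbers reproduce any
published absolute result. The package's acceptance checks are therefore
identities on published *printed* numbers plus engine properties, never
equalities between fixture-driven outputs and published absolute totals.

## Problem sizes used in testing

The suite exercises the full 65-state, 43-cycle model for base-case and
scenario properties; a 10-year-horizon variant for multi-run properties
(DSA determinism, discount monotonicity); toy models of 2–5 states for
oracle equivalence (100 random instances against a loop-based reference at
1e-10); PSA reproducibility at 40–100 iterations and the degenerate-PSA
limit at the full 1,000 iterations; sampler moments at 10,000 draws. These
sizes were chosen to exercise every code path at full fidelity while
keeping the default test run in the low minutes.

## Known limitations

* Cohort means only — no microsimulation, no individual-level weight
  variability, no tunnel states for post-event years.
* Complications are absorbing; no remission, no recurrent-event counting
  beyond the acute-event cost attachment.
* Independent PSA draws; no correlation matrix, no EVPI/EVPPI.
* The risk calibrations are single-covariate (BMI) log-linear stand-ins;
  pathways not mediated through BMI are not captured.
* Only two comparators; no efficiency frontier.
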