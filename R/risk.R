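#' Annual incidence from a calibrated BMI risk function
#'
#' The model maps BMI to complication incidence through a pluggable
#' log-linear interface calibrated per condition: an annual base rate at a
#' reference BMI, a log relative risk per BMI unit, and optional covariate
#' hazard multipliers applied at cohort prevalence (a multiplier `m` active
#' in a fraction `x` of the cohort contributes `1 + x * (m - 1)` to the
#' cohort-mean rate). Users with full published risk-equation coefficients
#' can replace any calibration through the configuration.
#'
#' @param rf risk function: list with `base_annual_rate`, `reference_bmi`,
#'   `log_rr_per_bmi_unit`, and optionally `covariate_multipliers` (named).
#' @param bmi BMI in kg/m2 (> 0), vectorized.
#' @param covariates named numeric vector/list of covariate prevalences (or
#'   0/1 indicators). Every covariate named by the risk function's
#'   multipliers must be present; unknown lookups error.
#' @return annual probability (capped at 1).
#' @examples
#' rf <- list(base_annual_rate = 0.02, reference_bmi = 30,
#'            log_rr_per_bmi_unit = log(1.1), covariate_multipliers = list())
#' annual_incidence(rf, 31)  # 0.022
#' @export
annual_incidence <- function(rf, bmi, covariates = NULL) {
  stopifnot(all(bmi > 0))
  mult <- 1
  cm <- rf$covariate_multipliers
  if (length(cm)) {
    for (nm in names(cm)) {
      x <- covariates[[nm]]
      if (is.null(x) || is.na(x))
        stop("unknown covariate key '", nm, "' required by risk function",
             call. = FALSE)
      mult <- mult * (1 + x * (cm[[nm]] - 1))
    }
  }
  pmin(1, rf$base_annual_rate *
         exp(rf$log_rr_per_bmi_unit * (bmi - rf$reference_bmi)) * mult)
}

#' Convert an annual probability to a cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - annual_p)^cycle_len`, so four
#' quarterly cycles compound back to the annual probability exactly.
#'
#' @param annual_p annual probability in \[0, 1\].
#' @param cycle_len cycle length in years (> 0).
#' @return per-cycle probability.
#' @examples
#' prob_for_cycle(0.04, 0.25)  # 1 - 0.96^0.25
#' @export
prob_for_cycle <- function(annual_p, cycle_len) {
  stopifnot(all(annual_p >= 0), all(annual_p <= 1), all(cycle_len > 0))
  1 - (1 - annual_p)^cycle_len
}

#' All-cause annual death probability from the parametric life table
#'
#' Gompertz-Makeham hazard `h(age) = makeham + b_sex * exp(theta * age)`
#' converted to an annual probability. Lookup uses `floor(age)`; ages outside
#' the configured table range error (no extrapolation).
#'
#' @param mortality the `mortality` block of the configuration.
#' @param age age(s) in years.
#' @param sex `"female"`, `"male"`, or a numeric female fraction for a mixed
#'   cohort.
#' @return annual death probability.
#' @export
life_table_q <- function(mortality, age, sex) {
  g <- mortality$gompertz
  a <- floor(age)
  if (any(a < g$age_min) || any(a > g$age_max))
    stop("age ", paste(age[a < g$age_min | a > g$age_max], collapse = ", "),
         " outside life-table range [", g$age_min, ", ", g$age_max, "]",
         call. = FALSE)
  q_of <- function(b) 1 - exp(-(g$makeham + b * exp(g$theta * a)))
  if (is.character(sex)) {
    ff <- switch(sex, female = 1, male = 0,
                 stop("sex must be 'female', 'male' or a female fraction",
                      call. = FALSE))
  } else ff <- sex
  ff * q_of(g$b_female) + (1 - ff) * q_of(g$b_male)
}

bmi_hazard_ratio <- function(mortality, bmi) {
  if (!isTRUE(mortality$bmi_hr_enabled)) return(rep(1, length(bmi)))
  b <- mortality$bmi_hr_bands
  b$hr[findInterval(bmi, b$breaks) + 1L]
}

#' Residual background mortality
#'
#' All-cause mortality with deaths attributable to the explicitly modeled
#' diseases deducted proportionally (so disease mortality is added back
#' state-specifically without double counting), then scaled by the BMI-band
#' hazard ratio capturing residual excess mortality of higher BMI.
#'
#' @inheritParams life_table_q
#' @param bmi BMI in kg/m2.
#' @return annual probability: `q_all * (1 - sum(cause_fractions)) * HR(bmi)`,
#'   capped at 1.
#' @export
residual_mortality <- function(mortality, age, sex, bmi) {
  q <- life_table_q(mortality, age, sex)
  resid <- 1 - sum(unlist(mortality$cause_fractions))
  pmin(1, q * resid * bmi_hazard_ratio(mortality, bmi))
}

#' State-specific mortality including condition excess hazards
#'
#' Residual background mortality scaled by the product of per-condition
#' excess-mortality multipliers for the conditions present in the state
#' (probability-scale scaling, capped at 1), then converted to the cycle
#' length.
#'
#' @param mortality the `mortality` block of the configuration.
#' @param conditions character vector of conditions present (may be empty).
#' @param residual_annual annual residual mortality from
#'   [residual_mortality()].
#' @param cycle_len cycle length in years.
#' @return per-cycle death probability.
#' @export
state_excess_mortality <- function(mortality, conditions, residual_annual,
                                   cycle_len = 1) {
  mult <- 1
  for (cn in conditions) {
    m <- mortality$state_excess_multipliers[[cn]]
    if (is.null(m)) stop("no excess-mortality multiplier for '", cn, "'",
                         call. = FALSE)
    mult <- mult * m
  }
  prob_for_cycle(pmin(1, residual_annual * mult), cycle_len)
}
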