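#' Evaluate the baseline-utility regression polynomial
#'
#' The complication-free utility is a published regression on BMI (linear,
#' quadratic and cubic terms) with age, cardiovascular history, hypertension,
#' smoking status and prediabetes as covariates. Covariates may be supplied
#' as cohort-mean fractions rather than 0/1 indicators. This evaluator
#' returns the raw polynomial value; [baseline_utility()] applies the
#' \[0, 1\] clamp and the anchoring mode.
#'
#' @param coefs named list/vector of coefficients: `intercept`, `age`,
#'   `heart_circ`, `hypertension`, `smoke_current`, `smoke_previous`, `bmi`,
#'   `bmi2`, `bmi3`, `prediabetes`.
#' @param age,bmi numeric (vectorized).
#' @param heart_circ,hypertension,smoke_current,smoke_previous,prediabetes
#'   covariate indicators or cohort fractions.
#' @return raw regression utility value(s).
#' @examples
#' cfg <- default_config()
#' utility_regression(cfg$utilities$regression, age = 0, bmi = 0)  # intercept
#' @export
utility_regression <- function(coefs, age, bmi, heart_circ = 0,
                               hypertension = 0, smoke_current = 0,
                               smoke_previous = 0, prediabetes = 0) {
  coefs$intercept + coefs$age * age + coefs$heart_circ * heart_circ +
    coefs$hypertension * hypertension + coefs$smoke_current * smoke_current +
    coefs$smoke_previous * smoke_previous + coefs$bmi * bmi +
    coefs$bmi2 * bmi^2 + coefs$bmi3 * bmi^3 + coefs$prediabetes * prediabetes
}

cohort_regression_utility <- function(cfg, bmi, age) {
  ch <- cfg$cohort
  utility_regression(cfg$utilities$regression, age = age, bmi = bmi,
                     heart_circ = ch$cvd_history_fraction,
                     hypertension = ch$on_antihypertensive,
                     smoke_current = ch$smoker_fraction,
                     smoke_previous = ch$smoke_previous_fraction,
                     prediabetes = ch$prediabetes_fraction)
}

#' Complication-free cohort utility at a given BMI and age
#'
#' Two modes. `"regression"` evaluates the published regression directly at
#' the cohort covariates. `"fixed"` (default) anchors the cohort's baseline
#' utility at the published summary value (0.78) and moves it with the
#' regression's BMI/age gradient, i.e.
#' `0.78 + reg(bmi, age) - reg(bmi0, age0)`; this keeps the published level
#' while still letting utility respond dynamically to the BMI trajectory.
#' (The raw regression evaluated at the cohort means does not reproduce the
#' published 0.78 -- the two modes make that tension explicit.) The result is
#' clamped to \[0, 1\].
#'
#' @param cfg an `obemod_config`.
#' @param bmi BMI value(s), kg/m2.
#' @param age age value(s), years.
#' @param mode `"fixed"` or `"regression"`; defaults to the configured
#'   `model.baseline_utility_mode`.
#' @return utility value(s) in \[0, 1\].
#' @export
baseline_utility <- function(cfg, bmi, age, mode = NULL) {
  mode <- mode %||% cfg$model$baseline_utility_mode
  u <- if (mode == "regression") {
    cohort_regression_utility(cfg, bmi, age)
  } else {
    cfg$utilities$baseline_fixed +
      cohort_regression_utility(cfg, bmi, age) -
      cohort_regression_utility(cfg, cfg$cohort$bmi, cfg$cohort$age)
  }
  pmin(1, pmax(0, u))
}

#' State utility: baseline plus additive condition disutilities
#'
#' @param base complication-free utility.
#' @param conditions character vector of conditions present (subset of the
#'   modeled labels; empty for the no-complication state).
#' @param disutilities named list of per-condition disutilities (<= 0),
#'   e.g. `default_config()$utilities$state_disutilities`.
#' @return utility clamped to \[0, 1\].
#' @examples
#' du <- default_config()$utilities$state_disutilities
#' state_utility(0.78, "T2D", du)          # 0.751
#' state_utility(0.78, c("T2D", "CKD"), du)  # 0.702
#' @export
state_utility <- function(base, conditions, disutilities) {
  dec <- 0
  for (cn in conditions) {
    d <- disutilities[[cn]]
    if (is.null(d)) stop("unknown condition '", cn, "'", call. = FALSE)
    dec <- dec + d
  }
  pmin(1, pmax(0, base + dec))
}

#' One-time QALY decrement and cost of acute events
#'
#' Events enter as expected counts per cycle; each contributes a one-time
#' disutility (applied in the cycle of occurrence, discounting handled by
#' the engine) and an acute-care cost, split between fatal and non-fatal
#' tariffs where a fatal fraction is supplied.
#'
#' @param counts named numeric vector of expected event counts. Recognised
#'   names: `mi`, `angina`, `stroke`, `tia`, `gi_major`, `hypo_severe`,
#'   `hypo_nonsevere`.
#' @param event_costs named cost list (`<event>_fatal` / `<event>_nonfatal`
#'   pairs for events with a fatal split, a single entry otherwise), e.g.
#'   `default_config()$costs$event_costs`.
#' @param event_disutilities named disutility list (myocardial infarction
#'   and angina both map to the acute-coronary-syndrome disutility).
#' @param fatal_fractions named fatal fractions for split events (missing
#'   names are treated as non-fatal only).
#' @return list with `qaly` (total decrement, <= 0) and `cost`.
#' @examples
#' cc <- default_config()
#' event_qaly_and_cost(c(mi = 1), cc$costs$event_costs,
#'                     cc$utilities$event_disutilities)$cost  # 2724
#' @export
event_qaly_and_cost <- function(counts, event_costs, event_disutilities,
                                fatal_fractions = NULL) {
  stopifnot(all(counts >= 0))
  du_key <- c(mi = "acs", angina = "acs", stroke = "stroke", tia = "tia",
              gi_major = "gi_major", hypo_severe = "hypo_severe",
              hypo_nonsevere = "hypo_nonsevere")
  split_events <- c("mi", "angina", "stroke")
  qaly <- cost <- 0
  for (ev in names(counts)) {
    n <- counts[[ev]]
    if (n == 0) next
    if (is.na(du_key[ev])) stop("unknown event '", ev, "'", call. = FALSE)
    qaly <- qaly + n * event_disutilities[[du_key[ev]]]
    if (ev %in% split_events) {
      ff <- fatal_fractions[[ev]] %||% 0
      cost <- cost + n * (ff * event_costs[[paste0(ev, "_fatal")]] +
                            (1 - ff) * event_costs[[paste0(ev, "_nonfatal")]])
    } else {
      cost <- cost + n * event_costs[[ev]]
    }
  }
  list(qaly = qaly, cost = cost)
}

#' Payer drug cost of a set of dispensed packs
#'
#' `sum(packs * price) * payer_share`: the statutory co-payment share borne
#' by the patient is removed from the retail price. Cycles after treatment
#' stop simply dispense zero packs.
#'
#' @param pack_counts named numeric vector of packs by dose label.
#' @param prices named price list (euro per pack), e.g.
#'   `default_config()$costs$drug_prices`.
#' @param payer_share payer fraction of the retail price in \[0, 1\].
#' @return payer cost in euro.
#' @examples
#' drug_cost_cycle(c(sema_24 = 3), default_config()$costs$drug_prices, 0.75)
#' @export
drug_cost_cycle <- function(pack_counts, prices, payer_share = 1) {
  stopifnot(all(pack_counts >= 0), payer_share >= 0, payer_share <= 1)
  tot <- 0
  for (lbl in names(pack_counts)) {
    pr <- prices[[lbl]]
    if (is.null(pr)) stop("unknown dose label '", lbl, "'", call. = FALSE)
    tot <- tot + pack_counts[[lbl]] * pr
  }
  tot * payer_share
}

#' Per-cycle health-state cost
#'
#' Annual monitoring applies to every alive state (the no-complication state
#' therefore costs exactly the annual monitoring tariff); condition-specific
#' annual costs are additive on top, all pro-rated by cycle length.
#'
#' @param conditions character vector of conditions present (empty for the
#'   no-complication state).
#' @param costs the `costs` block of the configuration.
#' @param cycle_len cycle length in years.
#' @param monitoring include the universal monitoring cost (default `TRUE`;
#'   set `FALSE` for the convention where monitoring applies only to the
#'   no-complication state -- then supplied through
#'   `costs$noncomplication_extra`).
#' @return cost in euro for the cycle.
#' @examples
#' cc <- default_config()$costs
#' state_cost_cycle(character(0), cc, 1)  # 124.88
#' state_cost_cycle("T2D", cc, 1)         # 124.88 + 1125.91
#' @export
state_cost_cycle <- function(conditions, costs, cycle_len,
                             monitoring = TRUE) {
  tot <- if (monitoring) costs$monitoring_annual else 0
  if (length(conditions) == 0) tot <- tot + costs$noncomplication_extra
  for (cn in conditions) {
    sc <- costs$state_costs[[cn]]
    if (is.null(sc)) stop("unknown condition '", cn, "'", call. = FALSE)
    tot <- tot + sc
  }
  tot * cycle_len
}
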