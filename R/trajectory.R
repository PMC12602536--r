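# Weeks/years conversion used throughout the trajectory layer.
WEEKS_PER_YEAR <- 365.25 / 7

#' Classify 12-week treatment response
#'
#' The early stopping rule discontinues patients who fail to achieve at
#' least 5\% weight loss from baseline at the 12-week assessment. Weight
#' change is a signed fraction of baseline (loss negative); exactly 5.0\%
#' loss counts as response (the criterion is inclusive).
#'
#' @param weight_change_12w signed fractional weight change at 12 weeks.
#' @param threshold response threshold as a positive fraction (default 0.05).
#' @return logical: `TRUE` for responders.
#' @examples
#' classify_response(-0.050)  # TRUE: boundary is inclusive
#' classify_response(-0.049)  # FALSE
#' @export
classify_response <- function(weight_change_12w, threshold = 0.05) {
  weight_change_12w <= -threshold
}

#' Interpolate a %-weight-change timeline at a given week
#'
#' Linear interpolation between anchor weeks; beyond the last anchor the
#' effect plateaus at the last anchor value (treatment maintenance phase).
#'
#' @param timeline list with numeric `weeks` and `change` of equal length,
#'   starting at `(0, 0)`.
#' @param week assessment week(s), >= 0.
#' @return fractional weight change(s) from baseline (losses negative).
#' @export
timeline_change <- function(timeline, week) {
  if (is.null(timeline) || length(timeline$weeks) == 0)
    stop("empty efficacy timeline", call. = FALSE)
  stopifnot(all(week >= 0))
  if (length(timeline$weeks) == 1) return(rep(timeline$change, length(week)))
  stats::approx(timeline$weeks, timeline$change, xout = week, rule = 2)$y
}

#' On-treatment BMI at a given week
#'
#' Scales the baseline BMI by the arm's interpolated %-weight-change
#' timeline (percentage anchors scale to any baseline, which is why the
#' trajectory is driven by relative rather than absolute weight change).
#'
#' @param arm an arm configuration (element of `cfg$arms`) or a raw timeline
#'   list with `weeks`/`change`.
#' @param baseline_bmi baseline BMI in kg/m2.
#' @param week week(s) since treatment start.
#' @param estimand which timeline to use when `arm` is an arm configuration
#'   (defaults to the arm's configured estimand).
#' @return BMI in kg/m2.
#' @export
on_treatment_bmi <- function(arm, baseline_bmi, week, estimand = NULL) {
  tl <- if (!is.null(arm$weeks)) arm
        else arm$timelines[[estimand %||% arm$estimand]]
  baseline_bmi * (1 + timeline_change(tl, week))
}

#' Post-discontinuation catch-up interpolation
#'
#' After stopping treatment the residual effect decays linearly: the path
#' moves from the BMI at stop to the counterfactual (untreated) trajectory
#' over `catch_up_years`, after which it coincides with the counterfactual.
#'
#' @param bmi_at_stop BMI when treatment stopped.
#' @param counterfactual_bmi counterfactual-trajectory BMI evaluated at the
#'   same time point(s) as `years_since_stop`.
#' @param years_since_stop time since stopping, >= 0 (vectorized).
#' @param catch_up_years duration of the linear catch-up (> 0).
#' @return BMI in kg/m2.
#' @export
catch_up_bmi <- function(bmi_at_stop, counterfactual_bmi, years_since_stop,
                         catch_up_years) {
  stopifnot(all(years_since_stop >= 0), catch_up_years > 0)
  frac <- pmin(1, years_since_stop / catch_up_years)
  (1 - frac) * bmi_at_stop + frac * counterfactual_bmi
}

#' Natural BMI progression
#'
#' Untreated adults gain weight at a slow constant rate (base case
#' 0.47 kg/year); the rate is converted to BMI units through height squared,
#' or applied directly when `units = "bmi"`.
#'
#' @param bmi starting BMI, kg/m2.
#' @param years elapsed years, >= 0.
#' @param weight_gain_rate gain rate (kg/year or BMI-units/year).
#' @param height height in metres (> 0), used for `units = "kg"`.
#' @param units `"kg"` (default) or `"bmi"`.
#' @return BMI in kg/m2.
#' @examples
#' natural_progression(41.5, 1, 0.47, 1.70)  # 41.5 + 0.47/1.7^2
#' @export
natural_progression <- function(bmi, years, weight_gain_rate, height,
                                units = "kg") {
  stopifnot(height > 0, all(years >= 0))
  rate_bmi <- if (units == "kg") weight_gain_rate / height^2 else weight_gain_rate
  bmi + rate_bmi * years
}

# Pathway evaluators ---------------------------------------------------------
# All pathway functions map model time t (years since entry) to cohort-mean
# BMI. The common reference path N(t) starts natural drift at model entry so
# every pathway converges to the same counterfactual exactly.

natural_path_fn <- function(cfg) {
  m <- cfg$model; ch <- cfg$cohort
  function(t) natural_progression(ch$bmi, t, m$natural_weight_gain, ch$height,
                                  m$weight_gain_units)
}

diet_exercise_path_fn <- function(cfg, estimand = "treatment_policy") {
  m <- cfg$model; ch <- cfg$cohort
  tl <- cfg$arms$diet_exercise$timelines[[estimand]] %||%
    cfg$arms$diet_exercise$timelines$treatment_policy
  Nf <- natural_path_fn(cfg)
  t_end <- max(tl$weeks) / WEEKS_PER_YEAR
  bmi_end <- ch$bmi * (1 + timeline_change(tl, max(tl$weeks)))
  function(t) {
    on <- t <= t_end
    out <- numeric(length(t))
    out[on] <- ch$bmi * (1 + timeline_change(tl, t[on] * WEEKS_PER_YEAR))
    if (any(!on))
      out[!on] <- catch_up_bmi(bmi_end, Nf(t[!on]), t[!on] - t_end, m$catch_up_years)
    out
  }
}

# Counterfactual pathway a discontinuing patient reverts to.
counterfactual_fn <- function(cfg, estimand) {
  if (cfg$model$post_treatment_pathway == "natural") natural_path_fn(cfg)
  else diet_exercise_path_fn(cfg, estimand)
}

responder_subpath <- function(cfg, arm, t_stop, cf) {
  ch <- cfg$cohort; m <- cfg$model
  tl <- arm$timelines[[arm$estimand]]
  bmi_stop <- ch$bmi * (1 + timeline_change(tl, t_stop * WEEKS_PER_YEAR))
  function(t) {
    on <- t <= t_stop
    out <- numeric(length(t))
    out[on] <- ch$bmi * (1 + timeline_change(tl, t[on] * WEEKS_PER_YEAR))
    if (any(!on))
      out[!on] <- catch_up_bmi(bmi_stop, cf(t[!on]), t[!on] - t_stop, m$catch_up_years)
    out
  }
}

nonresponder_path_fn <- function(cfg, estimand) {
  m <- cfg$model; ch <- cfg$cohort
  Df <- diet_exercise_path_fn(cfg, estimand)
  if (m$post_treatment_pathway == "diet_exercise") return(Df)
  # no residual lifestyle benefit: revert from the 12-week value to N(t)
  Nf <- natural_path_fn(cfg)
  t12 <- m$stopping_rule_week / WEEKS_PER_YEAR
  bmi12 <- Df(t12)
  function(t) {
    early <- t <= t12
    out <- numeric(length(t))
    out[early] <- Df(t[early])
    if (any(!early))
      out[!early] <- catch_up_bmi(bmi12, Nf(t[!early]), t[!early] - t12, m$catch_up_years)
    out
  }
}

# AE-driven discontinuation: responders stop early with an annual probability
# converted to a hazard; stops are resolved at cycle boundaries after the
# 12-week assessment. Returns stop times and their weights (last = full
# duration).
ae_stop_distribution <- function(cfg) {
  m <- cfg$model
  bounds <- cumsum(m$cycle_schedule)
  t12 <- m$stopping_rule_week / WEEKS_PER_YEAR
  inner <- bounds[bounds > t12 + 1e-9 & bounds < m$max_treatment_years - 1e-9]
  list(times = c(inner, m$max_treatment_years), inner = inner)
}

#' Build the pathway-weighted per-cycle BMI path for one treatment arm
#'
#' Combines the responder pathway (on-treatment effect, possible early
#' adverse-event discontinuation at cycle boundaries, post-treatment linear
#' catch-up to the counterfactual, then natural progression) with the
#' non-responder pathway (diet-and-exercise trajectory from the 12-week
#' stopping-rule assessment onwards), weighted `(1 - non_responder_rate,
#' non_responder_rate)`. Also derives the on-drug cohort fraction over time
#' and the titration-aware payer drug + consumable cost per cycle.
#'
#' @param cfg an `obemod_config`.
#' @param arm_name one of `names(cfg$arms)`.
#' @return an `obemod_bmi_path`: list with per-cycle `t_start`, `t_mid`,
#'   `cycle_lengths`, pathway BMI columns (`bmi_responder`,
#'   `bmi_nonresponder`), pathway `weights`, cohort-mean `bmi_mid` and
#'   `bmi_start` (length cycles + 1, including the horizon end), average
#'   on-treatment fraction `f_on`, and per-alive-person `drug_cost` per
#'   cycle (payer perspective, consumables included).
#' @export
build_bmi_path <- function(cfg, arm_name) {
  arm <- cfg$arms[[arm_name]]
  if (is.null(arm)) stop("unknown arm: ", arm_name, call. = FALSE)
  m <- cfg$model
  lens <- m$cycle_schedule
  t_start <- c(0, cumsum(lens))[seq_along(lens)]
  t_mid <- t_start + lens / 2
  t_grid <- c(t_start, sum(lens))

  no_drug <- is.na(arm$maintenance_label %||% NA_character_)
  if (no_drug) {
    # lifestyle-only pathway: the maximum pharmacotherapy duration and
    # AE-discontinuation machinery do not apply
    resp_at <- diet_exercise_path_fn(cfg, arm$estimand)
  } else {
    cf <- counterfactual_fn(cfg, arm$estimand)
    stops <- ae_stop_distribution(cfg)
    p_ae <- min(max(arm$ae_discontinuation_rate, 0), 0.999999)
    h <- -log(1 - p_ae)
    surv <- exp(-h * stops$inner)
    w_stop <- c(-diff(c(1, surv)), if (length(surv)) surv[length(surv)] else 1)
    sub <- lapply(stops$times, function(s) responder_subpath(cfg, arm, s, cf))
    resp_at <- function(t) {
      acc <- 0
      for (j in seq_along(sub)) acc <- acc + w_stop[j] * sub[[j]](t)
      acc
    }
  }

  nr_path <- nonresponder_path_fn(cfg, arm$estimand)
  nr <- if (isTRUE(m$stopping_rule_enabled)) arm$non_responder_rate else 0
  weights <- c(responder = 1 - nr, nonresponder = nr)

  bmi_resp_mid <- resp_at(t_mid);  bmi_nr_mid <- nr_path(t_mid)
  bmi_resp_grid <- resp_at(t_grid); bmi_nr_grid <- nr_path(t_grid)
  bmi_mid <- weights[1] * bmi_resp_mid + weights[2] * bmi_nr_mid
  bmi_grid <- weights[1] * bmi_resp_grid + weights[2] * bmi_nr_grid

  dc <- drug_exposure(cfg, arm, weights[1])

  structure(list(
    arm = arm_name, cycle_lengths = lens, t_start = t_start, t_mid = t_mid,
    bmi_responder = bmi_resp_mid, bmi_nonresponder = bmi_nr_mid,
    weights = weights, bmi_mid = bmi_mid, bmi_grid = bmi_grid,
    f_on = dc$f_on_avg, drug_cost = dc$cost
  ), class = "obemod_bmi_path")
}

#' @export
print.obemod_bmi_path <- function(x, ...) {
  cat(sprintf("<obemod_bmi_path> arm '%s': %d cycles, BMI %.2f -> %.2f kg/m2\n",
              x$arm, length(x$cycle_lengths), x$bmi_mid[1],
              x$bmi_mid[length(x$bmi_mid)]))
  cat(sprintf("  pathway weights: responder %.3f / non-responder %.3f\n",
              x$weights[1], x$weights[2]))
  invisible(x)
}

#' Per-cycle BMI path as a tidy table
#' @param path an `obemod_bmi_path`.
#' @return tibble with one row per cycle.
#' @export
bmi_path_table <- function(path) {
  tibble::tibble(
    cycle = seq_along(path$cycle_lengths),
    t_start = path$t_start, cycle_length = path$cycle_lengths,
    t_mid = path$t_mid, bmi_responder = path$bmi_responder,
    bmi_nonresponder = path$bmi_nonresponder, bmi_mean = path$bmi_mid,
    f_on = path$f_on, drug_cost = path$drug_cost
  )
}

# Drug exposure and acquisition cost -----------------------------------------
# f_on(t): everyone is on drug until the 12-week assessment; afterwards the
# responder share remains, decayed by the AE-discontinuation hazard, until the
# maximum treatment duration. The per-cycle payer cost integrates the
# piecewise-constant titration price calendar against f_on exactly.
drug_exposure <- function(cfg, arm, responder_weight) {
  m <- cfg$model
  lens <- m$cycle_schedule
  t_start <- c(0, cumsum(lens))[seq_along(lens)]
  t12 <- min(m$stopping_rule_week / WEEKS_PER_YEAR, m$max_treatment_years)
  tmax <- m$max_treatment_years
  h <- -log(1 - min(max(arm$ae_discontinuation_rate, 0), 0.999999))

  no_drug <- is.na(arm$maintenance_label %||% NA_character_)
  packs_per_year <- if (no_drug) 0 else 365.25 / arm$pack_days
  # price calendar: (start-year, annual payer price rate)
  seg_t <- 0
  seg_rate <- numeric(0)
  if (!no_drug) {
    tit_w <- arm$titration$weeks
    tit_l <- arm$titration$labels
    tcum <- c(0, cumsum(tit_w)) / WEEKS_PER_YEAR
    for (i in seq_along(tit_l))
      seg_rate <- c(seg_rate, cfg$costs$drug_prices[[tit_l[i]]] *
                      packs_per_year * m$payer_share)
    seg_rate <- c(seg_rate, cfg$costs$drug_prices[[arm$maintenance_label]] *
                    packs_per_year * m$payer_share)
    seg_t <- tcum
  } else seg_rate <- 0
  # consumables are a flat tariff while on treatment (no drug co-payment)
  cons_rate <- if (no_drug) 0 else cfg$costs$consumables_annual

  price_at <- function(t) {
    i <- findInterval(t, seg_t)
    seg_rate[pmax(1, pmin(i, length(seg_rate)))]
  }
  f_on_coef <- function(t) { # returns (a, use_exp): f_on = a * exp(-h t) or a
    if (t >= tmax) return(c(0, 0))
    if (t < t12) return(c(1, 0))
    c(responder_weight, 1)
  }
  integrate_cycle <- function(a, b) {
    brk <- sort(unique(c(a, b, seg_t[seg_t > a & seg_t < b],
                         t12[t12 > a & t12 < b], tmax[tmax > a & tmax < b])))
    cost <- 0; fint <- 0
    for (k in seq_len(length(brk) - 1)) {
      lo <- brk[k]; hi <- brk[k + 1]; mid <- (lo + hi) / 2
      co <- f_on_coef(mid)
      if (co[1] == 0) next
      seg_f <- if (co[2] == 0) co[1] * (hi - lo)
               else if (h > 0) co[1] * (exp(-h * lo) - exp(-h * hi)) / h
               else co[1] * (hi - lo)
      r <- price_at(mid) + cons_rate
      cost <- cost + r * seg_f
      fint <- fint + seg_f
    }
    c(cost, fint)
  }
  out <- vapply(seq_along(lens), function(i)
    integrate_cycle(t_start[i], t_start[i] + lens[i]), numeric(2))
  list(cost = out[1, ], f_on_avg = out[2, ] / lens)
}
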