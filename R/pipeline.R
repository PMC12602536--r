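#' Run the full cohort model for one treatment arm
#'
#' Builds the arm's BMI path, derives per-cycle incidence and mortality from
#' it, assembles the per-cycle transition matrices over the 65-state
#' comorbidity space, constructs utility and cost reward matrices (baseline
#' utility moving with BMI and age, additive state disutilities; universal
#' monitoring plus condition state costs; titration-aware drug costs;
#' acute-event costs and disutilities for new acute coronary syndrome,
#' stroke, transient ischaemic attacks and on-treatment adverse events), and
#' accumulates half-cycle-corrected discounted costs, QALYs and life-years.
#'
#' @param cfg an `obemod_config`.
#' @param arm_name one of `names(cfg$arms)`.
#' @param keep_trace keep the per-cycle audit trace (slower).
#' @return list with `result` (costs by component -- `treatment`,
#'   `monitoring`, `state`, `event` -- and total; `qalys`; `lys`), `trace`,
#'   `path` (the `obemod_bmi_path`) and `space`.
#' @export
.obemod_cache <- new.env(parent = emptyenv())

# the default 65-state space and its acquisition structure are constants;
# cache them across runs (PSA/DSA rerun the pipeline thousands of times)
default_space_struct <- function() {
  if (is.null(.obemod_cache$space)) {
    .obemod_cache$space <- state_space()
    .obemod_cache$struct <- transition_structure(.obemod_cache$space)
  }
  list(space = .obemod_cache$space, struct = .obemod_cache$struct)
}

run_arm <- function(cfg, arm_name, keep_trace = FALSE) {
  path <- build_bmi_path(cfg, arm_name)
  ss <- default_space_struct()
  space <- ss$space
  struct <- ss$struct
  engine_inputs <- assemble_engine_inputs(cfg, path, space, struct)
  out <- run_cohort(
    matrices = engine_inputs$matrices,
    cycle_lengths = cfg$model$cycle_schedule,
    utility = engine_inputs$utility,
    cost_components = engine_inputs$cost_components,
    alive = engine_inputs$alive,
    init = engine_inputs$init,
    discount_costs = cfg$model$discount_rate_costs,
    discount_outcomes = cfg$model$discount_rate_outcomes,
    discount_timing = cfg$model$discount_timing,
    percycle_cost_components = engine_inputs$percycle_cost_components,
    percycle_qaly = engine_inputs$percycle_qaly,
    acquisition_events = engine_inputs$acquisition_events,
    keep_trace = keep_trace
  )
  list(result = out$result, trace = out$trace, path = path, space = space)
}

# Build matrices and reward structures for one arm run. Shared by run_arm;
# split out so tests can inspect the assembled inputs.
assemble_engine_inputs <- function(cfg, path, space, struct) {
  m <- cfg$model; ch <- cfg$cohort
  lens <- m$cycle_schedule
  C <- length(lens)
  S <- space$n
  conds <- space$conditions

  # per-state multipliers / reward ingredients
  excess_mult <- apply(space$membership, 1, function(mem) {
    prod(unlist(cfg$mortality$state_excess_multipliers[conds[mem]]) %||% 1)
  })
  du_sum <- apply(space$membership, 1, function(mem) {
    sum(unlist(cfg$utilities$state_disutilities[conds[mem]]))
  })
  sc_state <- apply(space$membership, 1, function(mem) {
    sum(unlist(cfg$costs$state_costs[conds[mem]]))
  })
  sc_state[1] <- sc_state[1] + cfg$costs$noncomplication_extra

  alive <- c(rep(TRUE, space$n_alive), FALSE)
  init <- c(1, rep(0, S - 1))

  # per-cycle incidences and mortality
  rf_list <- cfg$risks$conditions[conds]
  matrices <- vector("list", C)
  bu <- baseline_utility(cfg, path$bmi_mid, ch$age + path$t_mid)
  utility <- matrix(0, S, C)
  state_cost <- matrix(0, S, C)
  monitoring <- matrix(0, S, C)
  ev_cost <- numeric(C); ev_qaly <- numeric(C)

  ec <- cfg$costs$event_costs
  edu <- cfg$utilities$event_disutilities
  acs_spec <- cfg$risks$acs_event
  acs_cost <- acs_spec$mi_share *
    (acs_spec$fatal_fraction * ec$mi_fatal +
       (1 - acs_spec$fatal_fraction) * ec$mi_nonfatal) +
    (1 - acs_spec$mi_share) *
    (acs_spec$fatal_fraction * ec$angina_fatal +
       (1 - acs_spec$fatal_fraction) * ec$angina_nonfatal)
  stroke_rf <- cfg$risks$acute_events$stroke
  tia_rf <- cfg$risks$acute_events$tia
  stroke_cost <- stroke_rf$fatal_fraction * ec$stroke_fatal +
    (1 - stroke_rf$fatal_fraction) * ec$stroke_nonfatal

  for (cy in seq_len(C)) {
    bmi <- path$bmi_mid[cy]
    age_mid <- ch$age + path$t_mid[cy]
    p_ann <- vapply(rf_list, annual_incidence, numeric(1),
                    bmi = bmi, covariates = ch)
    p_cyc <- stats::setNames(prob_for_cycle(p_ann, lens[cy]), conds)
    q_res <- residual_mortality(cfg$mortality, age_mid, ch$female_fraction, bmi)
    pd <- prob_for_cycle(pmin(1, q_res * excess_mult), lens[cy])
    matrices[[cy]] <- build_transition_matrix(space, p_cyc, pd, struct)

    utility[seq_len(space$n_alive), cy] <-
      pmin(1, pmax(0, bu[cy] + du_sum))
    state_cost[seq_len(space$n_alive), cy] <- sc_state
    monitoring[seq_len(space$n_alive), cy] <- cfg$costs$monitoring_annual

    p_stroke <- annual_incidence(stroke_rf, bmi, ch)
    p_tia <- annual_incidence(tia_rf, bmi, ch)
    arm <- cfg$arms[[path$arm]]
    f_on <- path$f_on[cy]
    ev_cost[cy] <- lens[cy] *
      (p_stroke * stroke_cost + p_tia * ec$tia +
         f_on * (arm$gi_event_rate * ec$gi_major +
                   arm$hypo_nonsevere_rate * ec$hypo_nonsevere +
                   arm$hypo_severe_rate * ec$hypo_severe))
    ev_qaly[cy] <- lens[cy] *
      (p_stroke * edu$stroke + p_tia * edu$tia +
         f_on * (arm$gi_event_rate * edu$gi_major +
                   arm$hypo_nonsevere_rate * edu$hypo_nonsevere +
                   arm$hypo_severe_rate * edu$hypo_severe))
  }

  # transitions that acquire ACS carry a one-time acute event cost/disutility
  acs_mask <- matrix(0, S, S)
  acs_entries <- struct$cond == match("ACS", conds)
  acs_mask[cbind(struct$rows[acs_entries], struct$cols[acs_entries])] <- 1

  list(
    matrices = matrices,
    utility = utility,
    cost_components = list(monitoring = monitoring, state = state_cost),
    alive = alive, init = init,
    percycle_cost_components = list(treatment = path$drug_cost,
                                    event = ev_cost),
    percycle_qaly = ev_qaly,
    acquisition_events = list(list(mask = acs_mask, cost = acs_cost,
                                   qaly = edu$acs, component = "event"))
  )
}

#' Run the base-case comparison of two arms
#'
#' Runs the cohort model for the intervention and comparator arms under the
#' same configuration and derives the decision metrics.
#'
#' @param cfg an `obemod_config` (default: the packaged base case).
#' @param intervention,comparator arm names (default semaglutide vs
#'   liraglutide).
#' @return an `obemod_run`: list with per-arm `results`, the
#'   `obemod_comparison`, a formatted `table`, and the configuration.
#' @examples
#' \donttest{
#' run <- run_comparison(default_config())
#' run$comparison
#' }
#' @export
run_comparison <- function(cfg = default_config(),
                           intervention = "semaglutide",
                           comparator = "liraglutide") {
  a <- run_arm(cfg, intervention)
  b <- run_arm(cfg, comparator)
  cmp <- compare_arms(a$result, b$result, cfg$model$wtp_thresholds)
  structure(list(
    arms = stats::setNames(list(a$result, b$result),
                           c(intervention, comparator)),
    comparison = cmp,
    table = comparison_table(a$result, b$result, cmp,
                             arm_names = c(intervention, comparator)),
    config = cfg
  ), class = "obemod_run")
}

#' @export
print.obemod_run <- function(x, ...) {
  cat(sprintf("<obemod_run> %s vs %s over %g years\n",
              names(x$arms)[1], names(x$arms)[2], x$config$model$horizon_years))
  print(x$comparison)
  invisible(x)
}

#' Run the packaged scenario battery
#'
#' Applies each scenario of [scenario_specs()] (or a custom list) to the
#' base configuration, reruns the two-arm comparison, and tabulates
#' per-scenario totals, ICERs and the percent change versus the base-case
#' ICER.
#'
#' @param cfg base configuration.
#' @param specs named list of scenario specs.
#' @param base optional precomputed base `obemod_run` (avoids rerunning).
#' @return tibble with one row per scenario (base case first).
#' @export
run_scenarios <- function(cfg = default_config(), specs = scenario_specs(),
                          base = NULL) {
  base <- base %||% run_comparison(cfg)
  base_icer <- base$comparison$icer_qaly$value
  rows <- list(tibble::tibble(
    scenario = "Base case",
    cost_intervention = unname(base$arms[[1]]$costs["total"]),
    cost_comparator = unname(base$arms[[2]]$costs["total"]),
    qaly_intervention = base$arms[[1]]$qalys,
    qaly_comparator = base$arms[[2]]$qalys,
    icer = base_icer, pct_change_vs_base = 0))
  for (nm in names(specs)) {
    run <- run_comparison(apply_scenario(cfg, specs[[nm]]))
    ic <- run$comparison$icer_qaly$value
    rows[[length(rows) + 1]] <- tibble::tibble(
      scenario = specs[[nm]]$name %||% nm,
      cost_intervention = unname(run$arms[[1]]$costs["total"]),
      cost_comparator = unname(run$arms[[2]]$costs["total"]),
      qaly_intervention = run$arms[[1]]$qalys,
      qaly_comparator = run$arms[[2]]$qalys,
      icer = ic,
      pct_change_vs_base = 100 * (ic - base_icer) / base_icer)
  }
  do.call(rbind, rows)
}
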