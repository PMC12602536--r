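test_that("12-week response classification uses an inclusive 5% threshold", {
  expect_false(classify_response(-0.049))
  expect_true(classify_response(-0.050))
  expect_false(classify_response(0))
  expect_true(classify_response(-0.12))
})

test_that("on-treatment BMI interpolates the %-change timeline and plateaus", {
  tl <- list(weeks = c(0, 68), change = c(0, -0.10))
  expect_equal(on_treatment_bmi(tl, 41.5, 0), 41.5)
  expect_equal(on_treatment_bmi(tl, 41.5, 34), 41.5 * 0.95)
  expect_equal(on_treatment_bmi(tl, 41.5, 200), 41.5 * 0.90)  # plateau
  expect_error(timeline_change(list(weeks = numeric(0)), 10), "empty")
})

test_that("catch-up interpolation is linear and lands on the counterfactual", {
  expect_equal(catch_up_bmi(38, 41.5, 0, 3), 38)
  expect_equal(catch_up_bmi(38, 41.5, 1.5, 3), 39.75)   # midpoint
  expect_equal(catch_up_bmi(38, 41.5, 3, 3), 41.5)
  expect_equal(catch_up_bmi(38, 41.5, 7, 3), 41.5)      # beyond: counterfactual
})

test_that("natural progression converts kg/year through height squared", {
  expect_equal(natural_progression(41.5, 0, 0.47, 1.70), 41.5)
  expect_equal(natural_progression(41.5, 1, 0.47, 1.70), 41.5 + 0.47 / 1.70^2)
  expect_equal(natural_progression(41.5, 5, 0, 1.70), 41.5)
  # BMI-units mode applies the rate directly
  expect_equal(natural_progression(41.5, 2, 0.3, 1.70, units = "bmi"), 42.1)
})

test_that("cohort path mixes responder and non-responder pathways by rate", {
  cfg <- base_cfg()
  p <- build_bmi_path(cfg, "semaglutide")
  expect_equal(unname(p$weights), c(1 - 0.246, 0.246))
  expect_equal(p$bmi_mid,
               p$weights[1] * p$bmi_responder + p$weights[2] * p$bmi_nonresponder)

  # degenerate rates collapse to the pure pathways
  cfg0 <- config_set(cfg, "arms.semaglutide.non_responder_rate", 0)
  p0 <- build_bmi_path(cfg0, "semaglutide")
  expect_equal(p0$bmi_mid, p0$bmi_responder)
  cfg1 <- config_set(cfg, "arms.semaglutide.non_responder_rate", 1)
  p1 <- build_bmi_path(cfg1, "semaglutide")
  expect_equal(p1$bmi_mid, p1$bmi_nonresponder)
  # ... and the all-non-responder path is the diet-and-exercise path after
  # the assessment
  pde <- build_bmi_path(cfg1, "diet_exercise")
  late <- p1$t_mid > 0.25
  expect_equal(p1$bmi_mid[late], pde$bmi_mid[late], tolerance = 1e-9)
})

test_that("all arm paths converge to the common natural-progression path", {
  cfg <- base_cfg()
  drift <- cfg$model$natural_weight_gain / cfg$cohort$height^2
  natural <- cfg$cohort$bmi + drift * 0  # evaluated per cycle below
  for (arm in c("semaglutide", "liraglutide", "diet_exercise")) {
    p <- build_bmi_path(cfg, arm)
    n_at <- cfg$cohort$bmi + drift * p$t_mid
    conv <- p$t_mid > cfg$model$max_treatment_years + 2 * cfg$model$catch_up_years
    expect_true(any(conv))
    expect_lt(max(abs(p$bmi_mid[conv] - n_at[conv])), 1e-9)
  }
})

test_that("the better arm's cohort BMI dominates at every cycle and paths are continuous", {
  cfg <- base_cfg()
  ps <- build_bmi_path(cfg, "semaglutide")
  pl <- build_bmi_path(cfg, "liraglutide")
  expect_true(all(ps$bmi_mid <= pl$bmi_mid + 1e-12))
  for (p in list(ps, pl)) {
    expect_true(all(p$bmi_mid > 10 & p$bmi_mid < 100))
    # no jump larger than the largest single-cycle anchor change
    tl <- cfg$arms$semaglutide$timelines$treatment_policy
    max_anchor_step <- max(abs(diff(tl$change))) * cfg$cohort$bmi
    expect_lt(max(abs(diff(p$bmi_grid))), max_anchor_step + 0.5)
  }
})

test_that("drug exposure matches a day-by-day calendar walk for a full responder", {
  cfg <- base_cfg()
  cfg <- config_set(cfg, "arms.semaglutide.non_responder_rate", 0)
  cfg <- config_set(cfg, "arms.semaglutide.ae_discontinuation_rate", 0)
  p <- build_bmi_path(cfg, "semaglutide")
  total_drug <- sum(p$drug_cost)
  consumables <- cfg$costs$consumables_annual * cfg$model$max_treatment_years
  oracle <- walk_drug_cost(cfg$arms$semaglutide, cfg$costs$drug_prices,
                           cfg$model$payer_share, cfg$model$max_treatment_years)
  # day-grid walk vs exact integral: agreement to a fraction of one day's cost
  expect_equal(total_drug - consumables, oracle, tolerance = 2e-3)
  # nothing dispensed after treatment stops
  expect_true(all(p$drug_cost[p$t_start >= cfg$model$max_treatment_years] == 0))
})

test_that("disabling the stopping rule keeps the whole cohort on treatment", {
  cfg <- apply_scenario(base_cfg(),
                        scenario_specs()$trial_product_without_stopping_rule)
  p <- build_bmi_path(cfg, "semaglutide")
  expect_equal(unname(p$weights), c(1, 0))
  base <- build_bmi_path(base_cfg(), "semaglutide")
  expect_gt(sum(p$drug_cost), sum(base$drug_cost))
})
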