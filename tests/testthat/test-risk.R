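test_that("annual incidence follows the calibrated log-linear BMI link", {
  rf <- list(base_annual_rate = 0.02, reference_bmi = 30,
             log_rr_per_bmi_unit = log(1.1), covariate_multipliers = list())
  expect_equal(annual_incidence(rf, 30), 0.02)          # identity at reference
  expect_equal(annual_incidence(rf, 31), 0.022)          # one unit, RR 1.1
  rf0 <- rf; rf0$log_rr_per_bmi_unit <- 0
  expect_equal(annual_incidence(rf0, 55), 0.02)          # BMI-independent
  # capped at 1
  rf$base_annual_rate <- 0.9
  expect_equal(annual_incidence(rf, 80), 1)
})

test_that("cohort-prevalence covariate multipliers scale incidence and unknown keys error", {
  rf <- list(base_annual_rate = 0.01, reference_bmi = 30,
             log_rr_per_bmi_unit = 0,
             covariate_multipliers = list(smoker_fraction = 2))
  expect_equal(annual_incidence(rf, 30, list(smoker_fraction = 0)), 0.01)
  expect_equal(annual_incidence(rf, 30, list(smoker_fraction = 1)), 0.02)
  expect_equal(annual_incidence(rf, 30, list(smoker_fraction = 0.5)), 0.015)
  expect_error(annual_incidence(rf, 30, list(other = 1)), "unknown covariate")
})

test_that("incidence is nondecreasing in BMI for every modeled complication", {
  cfg <- base_cfg()
  bmis <- seq(20, 60, by = 2.5)
  for (cn in model_conditions()) {
    p <- annual_incidence(cfg$risks$conditions[[cn]], bmis, cfg$cohort)
    expect_true(all(diff(p) >= 0), info = cn)
  }
})

test_that("cycle conversion compounds exactly across sub-annual cycles", {
  expect_equal(prob_for_cycle(0, 0.25), 0)
  expect_equal(prob_for_cycle(0.3, 1), 0.3)
  expect_equal(prob_for_cycle(0.04, 0.25), 1 - 0.96^0.25)
  for (p in c(0.01, 0.2, 0.7)) {
    q <- prob_for_cycle(p, 0.25)
    expect_equal(1 - (1 - q)^4, p, tolerance = 1e-12)
  }
})

test_that("residual mortality deducts cause fractions and applies the BMI hazard ratio", {
  mo <- base_cfg()$mortality
  # hand case: q_all 0.01, 30% attributable, HR 1.5 -> 0.0105
  mo2 <- mo
  mo2$cause_fractions <- list(all = 0.3)
  mo2$bmi_hr_bands <- list(breaks = c(18.5, 25), hr = c(1, 1, 1.5))
  q_all <- life_table_q(mo2, 50, "female")
  expect_equal(residual_mortality(mo2, 50, "female", 30),
               q_all * 0.7 * 1.5)
  # no deduction, reference band: q_all unchanged
  mo3 <- mo
  mo3$cause_fractions <- list()
  expect_equal(residual_mortality(mo3, 50, "female", 22),
               life_table_q(mo3, 50, "female"))
  # reference band multiplier is exactly 1
  expect_equal(residual_mortality(mo, 60, 0.736, 22) /
                 (life_table_q(mo, 60, 0.736) *
                    (1 - sum(unlist(mo$cause_fractions)))), 1)
})

test_that("life table errors outside its range and q rises with age above 30", {
  mo <- base_cfg()$mortality
  expect_error(life_table_q(mo, 5, "male"), "outside")
  expect_error(life_table_q(mo, 200, "female"), "outside")
  q <- life_table_q(mo, 30:100, "male")
  expect_true(all(diff(q) > 0))
  # mixed-sex lookup is the female-fraction blend
  expect_equal(life_table_q(mo, 50, 0.736),
               0.736 * life_table_q(mo, 50, "female") +
                 0.264 * life_table_q(mo, 50, "male"))
})

test_that("state excess mortality composes multiplicatively and respects the floor", {
  mo <- base_cfg()$mortality
  r <- residual_mortality(mo, 55, 0.736, 41.5)
  expect_equal(state_excess_mortality(mo, character(0), r, 1), r)
  mo1 <- mo; mo1$state_excess_multipliers$T2D <- 1
  expect_equal(state_excess_mortality(mo1, "T2D", r, 1), r)
  # brute-force composition on a toy: p = min(1, r * m1 * m2), cycle-converted
  m1 <- mo$state_excess_multipliers$T2D
  m2 <- mo$state_excess_multipliers$CKD
  expect_equal(state_excess_mortality(mo, c("T2D", "CKD"), r, 0.25),
               1 - (1 - min(1, r * m1 * m2))^0.25)
  # any comorbid state dies at least as fast as the background
  for (cn in model_conditions())
    expect_gte(state_excess_mortality(mo, cn, r, 1), r)
  expect_error(state_excess_mortality(mo, "gout", r), "multiplier")
})

test_that("lower BMI paths accumulate less incidence for every complication", {
  cfg <- base_cfg()
  ps <- build_bmi_path(cfg, "semaglutide")
  pl <- build_bmi_path(cfg, "liraglutide")
  for (cn in model_conditions()) {
    rf <- cfg$risks$conditions[[cn]]
    cum_s <- sum(annual_incidence(rf, ps$bmi_mid, cfg$cohort) * ps$cycle_lengths)
    cum_l <- sum(annual_incidence(rf, pl$bmi_mid, cfg$cohort) * pl$cycle_lengths)
    expect_lte(cum_s, cum_l + 1e-12)
  }
})
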