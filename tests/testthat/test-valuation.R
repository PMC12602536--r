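test_that("the baseline-utility regression matches a term-by-term oracle", {
  coefs <- base_cfg()$utilities$regression
  expect_equal(utility_regression(coefs, age = 0, bmi = 0), 0.942975)
  set.seed(42)
  for (i in 1:1000) {
    age <- runif(1, 18, 90); bmi <- runif(1, 16, 60)
    cov <- runif(5)
    got <- utility_regression(coefs, age, bmi, heart_circ = cov[1],
                              hypertension = cov[2], smoke_current = cov[3],
                              smoke_previous = cov[4], prediabetes = cov[5])
    want <- poly_utility_oracle(coefs, age, bmi, heart_circ = cov[1],
                                hypertension = cov[2], smoke_current = cov[3],
                                smoke_previous = cov[4], prediabetes = cov[5])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # zeroing the BMI terms removes BMI dependence
  c0 <- coefs; c0$bmi <- c0$bmi2 <- c0$bmi3 <- 0
  expect_equal(utility_regression(c0, 50, 20), utility_regression(c0, 50, 55))
})

test_that("baseline-utility modes anchor and clamp as documented", {
  cfg <- base_cfg()
  # fixed mode: at the cohort's own baseline the utility is the published 0.78
  expect_equal(baseline_utility(cfg, cfg$cohort$bmi, cfg$cohort$age, "fixed"),
               0.78)
  # weight loss improves utility in the morbid-obesity range
  expect_gt(baseline_utility(cfg, 36, cfg$cohort$age), 0.78)
  # regression mode evaluates the raw polynomial at cohort covariates
  u_reg <- baseline_utility(cfg, cfg$cohort$bmi, cfg$cohort$age, "regression")
  expect_gt(abs(u_reg - 0.78), 0.01)  # the printed level differs from 0.78
  expect_true(all(baseline_utility(cfg, c(12, 41.5, 95), 50) >= 0 &
                    baseline_utility(cfg, c(12, 41.5, 95), 50) <= 1))
})

test_that("state utilities add disutilities and never increase with comorbidity", {
  du <- base_cfg()$utilities$state_disutilities
  expect_equal(state_utility(0.78, "T2D", du), 0.751)
  expect_equal(state_utility(0.78, character(0), du), 0.78)
  expect_equal(state_utility(0.78, c("T2D", "CKD"), du), 0.702)
  expect_error(state_utility(0.78, "gout", du), "unknown condition")
  sp <- state_space()
  u <- vapply(seq_len(sp$n_alive), function(i)
    state_utility(0.78, sp$conditions[sp$membership[i, ]], du), numeric(1))
  for (i in seq_len(sp$n_alive)) {
    for (k in which(!sp$membership[i, ])) {
      if (sp$size[i] >= 3) next
      j <- state_index(sp, c(sp$conditions[sp$membership[i, ]],
                             sp$conditions[k]))
      expect_lte(u[j], u[i])
    }
  }
})

test_that("event valuation prices fatal splits and books one-time disutilities", {
  cfg <- base_cfg()
  ec <- cfg$costs$event_costs
  edu <- cfg$utilities$event_disutilities
  one_mi <- event_qaly_and_cost(c(mi = 1), ec, edu)
  expect_equal(one_mi$cost, 2724.00)          # non-fatal by default
  expect_equal(one_mi$qaly, -0.129)
  expect_equal(event_qaly_and_cost(c(stroke = 1), ec, edu)$qaly, -0.181)
  expect_equal(event_qaly_and_cost(numeric(0), ec, edu),
               list(qaly = 0, cost = 0))
  split <- event_qaly_and_cost(c(mi = 2), ec, edu,
                               fatal_fractions = list(mi = 0.5))
  expect_equal(split$cost, 2 * (0.5 * 4166 + 0.5 * 2724))
  expect_error(event_qaly_and_cost(c(sneeze = 1), ec, edu), "unknown event")
})

test_that("drug cost applies the payer share to dispensed packs", {
  prices <- base_cfg()$costs$drug_prices
  expect_equal(drug_cost_cycle(c(sema_24 = 3), prices, 0.75),
               3 * 190.21 * 0.75)
  expect_equal(drug_cost_cycle(c(sema_24 = 3), prices, 1), 3 * 190.21)
  expect_equal(drug_cost_cycle(c(sema_24 = 0), prices, 0.75), 0)
  expect_error(drug_cost_cycle(c(unknown = 1), prices), "unknown dose label")
})

test_that("state costs are monitoring plus additive condition costs, pro-rated", {
  costs <- base_cfg()$costs
  expect_equal(state_cost_cycle(character(0), costs, 1), 124.88)
  expect_equal(state_cost_cycle("T2D", costs, 1), 124.88 + 1125.91)
  expect_equal(state_cost_cycle(c("T2D", "CKD"), costs, 0.25),
               (124.88 + 1125.91 + 811.46) / 4)
  expect_error(state_cost_cycle("gout", costs, 1), "unknown condition")
  # adding a condition never decreases cost
  sp <- state_space()
  cost_of <- vapply(seq_len(sp$n_alive), function(i)
    state_cost_cycle(sp$conditions[sp$membership[i, ]], costs, 1), numeric(1))
  for (i in seq_len(sp$n_alive)) {
    for (k in which(!sp$membership[i, ])) {
      if (sp$size[i] >= 3) next
      j <- state_index(sp, c(sp$conditions[sp$membership[i, ]],
                             sp$conditions[k]))
      expect_gte(cost_of[j], cost_of[i])
    }
  }
})
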