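test_that("state enumeration yields the expected counts and ordering", {
  sp <- state_space()
  expect_equal(sp$n, 65)  # 1 + 7 + 21 + 35 + 1
  expect_equal(sp$labels[1], "none")
  expect_equal(sp$labels[sp$death], "death")
  expect_equal(sum(sp$size == 1), 7)
  expect_equal(sum(sp$size == 2), 21)
  expect_equal(sum(sp$size == 3), 35)
  expect_false(any(duplicated(sp$labels)))
  # deterministic ordering: size then lexicographic in condition order
  expect_equal(sp$labels[2:3], c("T2D", "ACS"))
  expect_equal(sp$labels[9], "T2D+ACS")

  expect_equal(state_space(c("A"), 1)$n, 3)
  expect_equal(state_space(c("A", "B"), 2)$n, 5)
  expect_equal(state_index(sp, c("CKD", "T2D")),
               match("T2D+CKD", sp$labels))
})

test_that("transition matrices allocate mortality first, then normalized acquisitions", {
  sp1 <- state_space("X", 1)
  M <- build_transition_matrix(sp1, c(X = 0.2), c(0.1, 0.1))
  expect_equal(M[1, ], c(0.72, 0.18, 0.10))   # (1-0.1)*0.2 to the single state
  expect_equal(M[3, ], c(0, 0, 1))            # death absorbing

  sp <- state_space()
  p <- setNames(runif(7, 0, 0.2), model_conditions())
  M <- build_transition_matrix(sp, p, runif(sp$n_alive, 0, 0.1))
  expect_equal(rowSums(M), rep(1, sp$n), tolerance = 1e-9)
  expect_true(all(M >= 0 & M <= 1))
  # triple-condition states only stay or die
  triples <- which(sp$size == 3)
  for (i in triples) expect_equal(sum(M[i, -c(i, sp$death)]), 0)
  # zero incidence + zero mortality = identity
  M0 <- build_transition_matrix(sp, setNames(rep(0, 7), model_conditions()), 0)
  expect_equal(M0, diag(sp$n))
  # competing-risk normalization preserves total acquisition mass 1-prod(1-p)
  expect_equal(sum(build_transition_matrix(sp, p, 0)[1, 2:8]),
               1 - prod(1 - p), tolerance = 1e-12)
})

test_that("discounting follows (1+r)^(-t)", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(10, 0.035), 1.035^-10)
  expect_equal(discount_factor(c(3, 17), 0), c(1, 1))
})

test_that("half-cycle correction reproduces the two-cycle hand case", {
  M <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE)
  out <- run_cohort(list(M, M), c(1, 1),
                    utility = matrix(1, 2, 2) * c(1, 0),
                    cost_components = matrix(0, 2, 2),
                    alive = c(TRUE, FALSE), init = c(1, 0))
  expect_identical(out$result$lys, 1.125)  # (1+0.5)/2 + (0.5+0.25)/2
})

test_that("a deathless undiscounted cohort conserves exactly one life-year per year", {
  cfg <- base_cfg()
  sp <- state_space()
  lens <- cfg$model$cycle_schedule
  M <- diag(sp$n)
  out <- run_cohort(rep(list(M), length(lens)), lens,
                    utility = matrix(1, sp$n, length(lens)),
                    cost_components = matrix(0, sp$n, length(lens)),
                    alive = c(rep(TRUE, sp$n_alive), FALSE),
                    init = c(1, rep(0, sp$n - 1)))
  expect_equal(out$result$lys, 40, tolerance = 1e-9)
  expect_equal(out$result$qalys, 40, tolerance = 1e-9)
})

test_that("the cohort engine matches the naive loop oracle on random toys", {
  for (seed in 1:100) {
    toy <- make_toy_model(seed, n_states = 2 + seed %% 4,
                          n_cycles = 1 + seed %% 8)
    rates <- list(dc = 0.035 * (seed %% 3), do_ = 0.015 * (seed %% 2))
    got <- run_cohort(toy$matrices, toy$cycle_lengths, toy$utility,
                      toy$cost, toy$alive, toy$init,
                      discount_costs = rates$dc,
                      discount_outcomes = rates$do_)
    want <- naive_run_cohort(toy$matrices, toy$cycle_lengths, toy$utility,
                             toy$cost, toy$alive, toy$init,
                             discount_costs = rates$dc,
                             discount_outcomes = rates$do_)
    expect_equal(got$result$lys, want$lys, tolerance = 1e-10)
    expect_equal(got$result$qalys, want$qalys, tolerance = 1e-10)
    expect_equal(unname(got$result$costs["total"]), want$costs,
                 tolerance = 1e-10)
  }
})

test_that("mass is conserved, death absorbs, and the half-cycle bound holds", {
  cfg <- short_cfg()
  run <- run_arm(cfg, "semaglutide", keep_trace = TRUE)
  tr <- run$trace
  for (cy in unique(tr$cycle)) {
    occ <- tr$occupancy_end[tr$cycle == cy]
    expect_equal(sum(occ), 1, tolerance = 1e-9)
    expect_true(all(occ >= -1e-15))
  }
  death_occ <- tapply(tr$occupancy_end[tr$state == run$space$death],
                      tr$cycle[tr$state == run$space$death], sum)
  expect_true(all(diff(as.numeric(death_occ)) >= -1e-12))

  # undiscounted corrected LY lies strictly between start- and end-occupancy sums
  alive_states <- seq_len(run$space$n_alive)
  start_sum <- sum(tr$cycle_length[tr$state %in% alive_states] *
                     tr$occupancy_start[tr$state %in% alive_states])
  end_sum <- sum(tr$cycle_length[tr$state %in% alive_states] *
                   tr$occupancy_end[tr$state %in% alive_states])
  ly_undisc <- run$result$lys_undiscounted
  expect_gt(ly_undisc, end_sum)
  expect_lt(ly_undisc, start_sum)
})

test_that("discounted QALYs are nonincreasing in the discount rate", {
  cfg <- short_cfg()
  qalys <- vapply(c(0, 0.02, 0.035, 0.06), function(r) {
    c2 <- config_set(cfg, "model.discount_rate_outcomes", r)
    run_arm(c2, "semaglutide")$result$qalys
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("arm results are internally coherent (components, QALY<=LY bounds)", {
  run <- run_comparison(base_cfg())
  for (res in run$arms) {
    expect_equal(unname(res$costs["total"]),
                 sum(res$costs[c("treatment", "monitoring", "state", "event")]),
                 tolerance = 0.01)
    expect_lte(res$qalys, res$lys)
    expect_lte(res$lys, base_cfg()$model$horizon_years)
    expect_true(all(res$costs >= 0))
  }
})
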