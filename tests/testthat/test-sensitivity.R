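test_that("method-of-moments Beta and Gamma fits recover their targets", {
  b <- mm_beta(0.5, 0.1)
  expect_equal(b$alpha, 12)
  expect_equal(b$beta, 12)
  g <- mm_gamma(100, 20)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 4)
  # degenerate guard
  expect_equal(mm_beta(0.3, 0), list(point = 0.3))
  expect_equal(mm_gamma(100, 0), list(point = 100))
  expect_error(mm_beta(0.5, 0.6, "p"), "too large")
  expect_error(mm_gamma(-1, 2, "p"), "non-positive")
  # lognormal preserves the arithmetic mean
  ln <- mm_lognormal(1, 0.2)
  expect_equal(exp(ln$meanlog + ln$sdlog^2 / 2), 1, tolerance = 1e-12)
})

test_that("samplers recover mean and SE within Monte Carlo error at n = 10,000", {
  set.seed(7)
  n <- 10000
  # the published baseline utility with its published SE
  b <- mm_beta(0.78, 0.023)
  x <- rbeta(n, b$alpha, b$beta)
  expect_lt(abs(mean(x) - 0.78), 3 * 0.023 / sqrt(n))
  expect_lt(abs(sd(x) - 0.023), 3 * 0.023 / sqrt(2 * n))
  # a cost under the 20%-of-mean default rule
  g <- mm_gamma(100, 20)
  y <- rgamma(n, shape = g$shape, scale = g$scale)
  expect_lt(abs(mean(y) - 100), 3 * 20 / sqrt(n))
  expect_lt(abs(sd(y) - 20), 4 * 20 / sqrt(2 * n))
})

test_that("tornado items with no incremental leverage have zero span", {
  cfg <- short_cfg()
  items <- tibble::tibble(
    parameter = c("monitoring (both arms)", "degenerate range"),
    path = c("costs.monitoring_annual", "costs.state_costs.T2D"),
    low = c(124.88 * 0.75, 1125.91),
    high = c(124.88 * 1.25, 1125.91))
  res <- run_dsa(cfg, items, top = Inf)
  # monitoring applies identically per alive person-year in both arms; its
  # incremental effect is only the small survival difference
  expect_lt(res$span[res$parameter == "monitoring (both arms)"] /
              res$icer_base[1], 0.02)
  expect_equal(res$span[res$parameter == "degenerate range"], 0)
})

test_that("one-way sensitivity matches independent single runs and is deterministic", {
  cfg <- short_cfg()
  items <- dsa_default_items(cfg)[c(3, 11), ]  # T2D state cost, horizon
  res1 <- run_dsa(cfg, items, top = Inf)
  res2 <- run_dsa(cfg, items, top = Inf)
  expect_equal(res1, res2)  # identical config -> identical ranking
  # re-run oracle: evaluate one item by hand
  i <- which(res1$path == "costs.state_costs.T2D")
  lo <- run_comparison(config_set(cfg, "costs.state_costs.T2D",
                                  items$low[items$path == "costs.state_costs.T2D"]))
  hi <- run_comparison(config_set(cfg, "costs.state_costs.T2D",
                                  items$high[items$path == "costs.state_costs.T2D"]))
  expect_equal(res1$icer_low[i], lo$comparison$icer_qaly$value)
  expect_equal(res1$icer_high[i], hi$comparison$icer_qaly$value)
  expect_equal(res1$span[i], abs(res1$icer_high[i] - res1$icer_low[i]))
})

test_that("PSA is reproducible under a fixed seed and summaries are coherent", {
  cfg <- short_cfg()
  p1 <- run_psa(cfg, n = 40, seed = 11)
  p2 <- run_psa(cfg, n = 40, seed = 11)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg, n = 40, seed = 12)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))

  s <- p1$summary
  dq <- s[["delta_qaly"]]
  names(dq) <- s$statistic
  expect_gt(dq["sd"], 0)
  expect_lt(dq["lci95"], dq["mean"])
  expect_gt(dq["uci95"], dq["mean"])
  expect_true(all(p1$draws$cost_intervention >= 0))
  expect_true(all(p1$draws$qaly_intervention >= 0))
  # ~95% of draws inside the percentile interval by construction
  inside <- mean(p1$draws$delta_qaly >= dq["lci95"] &
                   p1$draws$delta_qaly <= dq["uci95"])
  expect_gte(inside, 0.9)
})

test_that("CEAC equals the NMB-positive fraction, is bounded, and has the right limits", {
  cfg <- short_cfg()
  psa <- run_psa(cfg, n = 60, seed = 3)
  d <- psa$draws
  cc <- ceac(d)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  for (i in seq_len(nrow(cc))) {
    lam <- cc$lambda[i]
    expect_equal(cc$probability[i],
                 mean(lam * d$delta_qaly - d$delta_cost > 0))
  }
  expect_equal(cc$probability[cc$lambda == 0], mean(d$delta_cost < 0))
  # decomposition: SE share plus NE draws whose ICER clears the threshold
  sh <- quadrant_shares(d)
  for (lam in c(9000, 27117, 34000)) {
    expect_equal(cc$probability[cc$lambda == lam],
                 unname(sh["SE"]) + mean(d$quadrant == "NE" & d$icer < lam),
                 tolerance = 1e-12)
  }
  # large-threshold limit: the fraction of draws with any QALY gain
  expect_equal(ceac(d, lambdas = 1e9)$probability[
    ceac(d, lambdas = 1e9)$lambda == 1e9],
    mean(d$delta_qaly > 0))
  expect_equal(sum(quadrant_shares(d)), 1)
})

test_that("the PSA parameter table assigns distributions by parameter type", {
  tab <- psa_parameter_table(base_cfg())
  expect_true(all(tab$dist[startsWith(tab$path, "costs.")] == "gamma"))
  expect_true(all(tab$dist[grepl("disutilit", tab$path)] == "beta"))
  expect_true(all(tab$dist[grepl("non_responder", tab$path)] == "beta"))
  expect_true(all(tab$dist[grepl("efficacy_multiplier", tab$path)] == "lognormal"))
  # default SE rule: 20% of the point estimate where no SE is published
  i <- which(tab$path == "costs.state_costs.T2D")
  expect_equal(tab$se[i], 0.2 * 1125.91)
  # published SEs are used where available
  j <- which(tab$path == "utilities.baseline_fixed")
  expect_equal(tab$se[j], 0.023)
})
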