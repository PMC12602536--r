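#' Method-of-moments Beta parameters
#'
#' For probabilities and utilities the probabilistic analysis draws from a
#' Beta distribution matched to the point estimate and standard error:
#' `nu = mean(1-mean)/se^2 - 1`, `alpha = mean*nu`, `beta = (1-mean)*nu`.
#' A standard error below `eps` collapses to a point mass (the degenerate
#' limit used to validate the PSA machinery).
#'
#' @param mean point estimate in (0, 1).
#' @param se standard error; must satisfy `se^2 < mean*(1-mean)`.
#' @param name parameter name used in error messages.
#' @param eps point-mass guard threshold.
#' @return list with `alpha`, `beta` (or `point = mean` when degenerate).
#' @examples
#' mm_beta(0.5, 0.1)  # alpha = beta = 12
#' @export
mm_beta <- function(mean, se, name = "parameter", eps = 1e-12) {
  stopifnot(mean > 0, mean < 1, se >= 0)
  if (se < eps) return(list(point = mean))
  if (se^2 >= mean * (1 - mean))
    stop("standard error too large for a Beta fit for '", name, "'",
         call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments Gamma parameters
#'
#' Costs are drawn from a Gamma distribution matched to the point estimate
#' and standard error: `shape = (mean/se)^2`, `scale = se^2/mean`.
#'
#' @inheritParams mm_beta
#' @return list with `shape`, `scale` (or `point = mean` when degenerate).
#' @examples
#' mm_gamma(100, 20)  # shape 25, scale 4
#' @export
mm_gamma <- function(mean, se, name = "parameter", eps = 1e-12) {
  if (mean <= 0 || se < 0)
    stop("non-positive mean or negative se for '", name, "'", call. = FALSE)
  if (se < eps) return(list(point = mean))
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Lognormal parameters for a multiplicative (relative-effect) parameter
#'
#' Relative effects are drawn on the log scale (positivity-preserving):
#' `sdlog^2 = log(1 + (se/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`, so
#' the draw's arithmetic mean equals the point estimate.
#'
#' @inheritParams mm_beta
#' @return list with `meanlog`, `sdlog` (or `point = mean`).
#' @export
mm_lognormal <- function(mean, se, name = "parameter", eps = 1e-12) {
  if (mean <= 0 || se < 0)
    stop("non-positive mean or negative se for '", name, "'", call. = FALSE)
  if (se < eps) return(list(point = mean))
  s2 <- log(1 + (se / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

draw_from <- function(dist, mean, se, name) {
  if (se <= 0) return(mean)
  switch(dist,
    beta = { p <- mm_beta(mean, se, name)
             if (!is.null(p$point)) p$point else stats::rbeta(1, p$alpha, p$beta) },
    gamma = { p <- mm_gamma(mean, se, name)
              if (!is.null(p$point)) p$point else stats::rgamma(1, shape = p$shape, scale = p$scale) },
    lognormal = { p <- mm_lognormal(mean, se, name)
                  if (!is.null(p$point)) p$point
                  else stats::rlnorm(1, p$meanlog, p$sdlog) },
    normal = stats::rnorm(1, mean, se),
    stop("unknown distribution '", dist, "'", call. = FALSE))
}

#' Parameters sampled by the probabilistic sensitivity analysis
#'
#' The sampled set and its distribution assignment: Gamma for costs (state,
#' event, monitoring, consumables), Beta for probabilities and utility
#' quantities (baseline utility with its published standard error,
#' disutility magnitudes with theirs, non-responder and adverse-event
#' rates, risk base rates), and Lognormal for multiplicative effects (an
#' arm-level efficacy multiplier scaling the whole \%-weight-change
#' timeline, and the natural weight-gain rate). Where no standard error is
#' published the default rule `se = default_se_fraction * mean` applies
#' (base case 20\%). Regulated drug tariffs are treated as certain and not
#' sampled. Parameters are drawn independently.
#'
#' @param cfg an `obemod_config`.
#' @return tibble with columns `path`, `dist`, `mean`, `se`, `transform`
#'   (`"identity"` or `"negate"`, the latter for disutilities sampled on
#'   their magnitude).
#' @export
psa_parameter_table <- function(cfg) {
  fr <- cfg$psa$default_se_fraction
  rows <- list()
  add <- function(path, dist, mean, se, transform = "identity") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      path = path, dist = dist, mean = mean, se = se, transform = transform)
  }
  for (nm in names(cfg$costs$state_costs))
    add(paste0("costs.state_costs.", nm), "gamma",
        cfg$costs$state_costs[[nm]], fr * cfg$costs$state_costs[[nm]])
  for (nm in names(cfg$costs$event_costs))
    add(paste0("costs.event_costs.", nm), "gamma",
        cfg$costs$event_costs[[nm]], fr * cfg$costs$event_costs[[nm]])
  add("costs.monitoring_annual", "gamma", cfg$costs$monitoring_annual,
      fr * cfg$costs$monitoring_annual)
  add("costs.consumables_annual", "gamma", cfg$costs$consumables_annual,
      fr * cfg$costs$consumables_annual)
  add("utilities.baseline_fixed", "beta", cfg$utilities$baseline_fixed,
      cfg$utilities$baseline_fixed_se)
  for (nm in names(cfg$utilities$state_disutilities))
    add(paste0("utilities.state_disutilities.", nm), "beta",
        -cfg$utilities$state_disutilities[[nm]],
        cfg$utilities$state_disutility_se[[nm]], "negate")
  for (nm in names(cfg$utilities$event_disutilities))
    add(paste0("utilities.event_disutilities.", nm), "beta",
        -cfg$utilities$event_disutilities[[nm]],
        cfg$utilities$event_disutility_se[[nm]], "negate")
  for (an in c("semaglutide", "liraglutide")) {
    arm <- cfg$arms[[an]]
    add(paste0("arms.", an, ".non_responder_rate"), "beta",
        arm$non_responder_rate, fr * arm$non_responder_rate)
    add(paste0("arms.", an, ".ae_discontinuation_rate"), "beta",
        arm$ae_discontinuation_rate, fr * arm$ae_discontinuation_rate)
    add(paste0("arms.", an, ".efficacy_multiplier"), "lognormal", 1, fr)
  }
  for (nm in names(cfg$risks$conditions))
    add(paste0("risks.conditions.", nm, ".base_annual_rate"), "beta",
        cfg$risks$conditions[[nm]]$base_annual_rate,
        fr * cfg$risks$conditions[[nm]]$base_annual_rate)
  add("model.natural_weight_gain", "lognormal", cfg$model$natural_weight_gain,
      fr * cfg$model$natural_weight_gain)
  do.call(rbind, rows)
}

# Apply one joint draw of the PSA parameter table to a config. The
# efficacy_multiplier pseudo-paths scale every anchor of the arm's active
# timelines; clamping of out-of-range draws is counted.
apply_psa_draw <- function(cfg, params, se_scale = 1) {
  clamped <- 0L
  for (i in seq_len(nrow(params))) {
    pth <- params$path[i]
    val <- draw_from(params$dist[i], params$mean[i], se_scale * params$se[i],
                     pth)
    if (params$transform[i] == "negate") val <- -val
    if (grepl("efficacy_multiplier$", pth)) {
      an <- split_path(pth)[2]
      for (tl in names(cfg$arms[[an]]$timelines)) {
        ch <- cfg$arms[[an]]$timelines[[tl]]$change * val
        if (any(ch < -0.9)) { ch <- pmax(ch, -0.9); clamped <- clamped + 1L }
        cfg$arms[[an]]$timelines[[tl]]$change <- ch
      }
    } else {
      if (params$dist[i] == "beta" && params$transform[i] == "identity" &&
          (val <= 0 || val >= 1)) { val <- min(max(val, 1e-9), 1 - 1e-9)
                                    clamped <- clamped + 1L }
      cfg <- config_set(cfg, pth, val)
    }
  }
  list(config = cfg, clamped = clamped)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: each iteration draws every sampled parameter
#' independently from its assigned distribution, reruns the full two-arm
#' model, and records per-arm discounted costs and QALYs with their
#' increments. Reproducible for a fixed seed.
#'
#' @param cfg an `obemod_config`.
#' @param n number of iterations (default from `cfg$psa$n_iterations`).
#' @param seed RNG seed.
#' @param se_scale multiplier on all standard errors (0 gives the
#'   degenerate point-mass limit in which every draw equals the base case).
#' @param intervention,comparator arm names.
#' @return an `obemod_psa`: list with `draws` (tibble: iteration, per-arm
#'   cost/qaly, `delta_cost`, `delta_qaly`, `icer`, `quadrant`, `clamped`),
#'   `summary` (see [psa_summary()]), and the base configuration.
#' @export
run_psa <- function(cfg = default_config(), n = NULL, seed = 1L,
                    se_scale = 1, intervention = "semaglutide",
                    comparator = "liraglutide") {
  n <- n %||% cfg$psa$n_iterations
  stopifnot(n >= 1)
  params <- psa_parameter_table(cfg)
  set.seed(as.integer(seed))
  cost_a <- cost_b <- qaly_a <- qaly_b <- numeric(n)
  clamped <- integer(n)
  for (i in seq_len(n)) {
    dr <- apply_psa_draw(cfg, params, se_scale)
    a <- run_arm(dr$config, intervention)$result
    b <- run_arm(dr$config, comparator)$result
    cost_a[i] <- unname(a$costs["total"]); qaly_a[i] <- a$qalys
    cost_b[i] <- unname(b$costs["total"]); qaly_b[i] <- b$qalys
    clamped[i] <- dr$clamped
  }
  d_cost <- cost_a - cost_b; d_qaly <- qaly_a - qaly_b
  draws <- tibble::tibble(
    iteration = seq_len(n),
    cost_intervention = cost_a, qaly_intervention = qaly_a,
    cost_comparator = cost_b, qaly_comparator = qaly_b,
    delta_cost = d_cost, delta_qaly = d_qaly,
    icer = ifelse(d_qaly != 0, d_cost / d_qaly, NA_real_),
    quadrant = ce_quadrant(d_cost, d_qaly),
    clamped = clamped
  )
  structure(list(draws = draws, summary = psa_summary(draws), config = cfg,
                 seed = seed, n = n),
            class = "obemod_psa")
}

#' @export
print.obemod_psa <- function(x, ...) {
  cat(sprintf("<obemod_psa> %d iterations (seed %s)\n", x$n, x$seed))
  print(x$summary)
  sh <- quadrant_shares(x$draws)
  cat(sprintf("  quadrants: SE (dominant) %.1f%%, NE %.1f%%, NW %.1f%%, SW %.1f%%\n",
              100 * sh["SE"], 100 * sh["NE"], 100 * sh["NW"], 100 * sh["SW"]))
  invisible(x)
}

#' Summarize PSA draws
#'
#' Mean, SD, percentile 95\% interval, minimum and maximum for per-arm costs
#' and QALYs and their increments.
#'
#' @param draws the `draws` tibble of an [run_psa()] result.
#' @return tibble with one row per statistic.
#' @export
psa_summary <- function(draws) {
  cols <- c("cost_intervention", "qaly_intervention",
            "cost_comparator", "qaly_comparator", "delta_cost", "delta_qaly")
  stat <- function(f) vapply(cols, function(cn) f(draws[[cn]]), numeric(1))
  mat <- rbind(mean = stat(mean), sd = stat(stats::sd),
               lci95 = stat(function(v) stats::quantile(v, 0.025, names = FALSE)),
               uci95 = stat(function(v) stats::quantile(v, 0.975, names = FALSE)),
               min = stat(min), max = stat(max))
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- cbind(tibble::tibble(statistic = rownames(mat)), out)
  tibble::as_tibble(out)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability of cost-
#' effectiveness is the fraction of draws with positive net monetary
#' benefit.
#'
#' @param draws the `draws` tibble of an [run_psa()] result.
#' @param lambdas threshold grid (default 0 to 50,000 by 500, always
#'   including 9,000, 27,117, 30,000 and 34,000).
#' @return tibble with `lambda` and `probability`.
#' @export
ceac <- function(draws, lambdas = NULL) {
  stopifnot(nrow(draws) > 0)
  lambdas <- sort(unique(c(lambdas %||% seq(0, 50000, by = 500),
                           9000, 27117, 30000, 34000)))
  prob <- vapply(lambdas, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  tibble::tibble(lambda = lambdas, probability = prob)
}

#' Cost-effectiveness plane quadrant shares
#'
#' @param draws the `draws` tibble of an [run_psa()] result.
#' @return named numeric vector of fractions over `NE`, `SE`, `NW`, `SW`
#'   (summing to 1).
#' @export
quadrant_shares <- function(draws) {
  stopifnot(nrow(draws) > 0)
  q <- factor(draws$quadrant, levels = c("NE", "SE", "NW", "SW"))
  prop.table(table(q))[c("NE", "SE", "NW", "SW")] |> c()
}

#' Default one-way sensitivity items
#'
#' Key clinical and economic inputs varied one at a time; each gets
#' `[low, high] = [0.75, 1.25] * base` unless an empirical range is
#' configured (the conservative +/-25\% convention used when no standard
#' error or interval is published).
#'
#' @param cfg an `obemod_config`.
#' @param rel_range relative half-width (default 0.25).
#' @return tibble with `parameter`, `path`, `low`, `high`.
#' @export
dsa_default_items <- function(cfg, rel_range = 0.25) {
  paths <- c(
    "costs.drug_prices.sema_24", "costs.drug_prices.lira_3",
    "costs.state_costs.T2D", "costs.state_costs.ACS",
    "costs.state_costs.OSA", "costs.state_costs.hypertension",
    "costs.monitoring_annual",
    "utilities.baseline_fixed",
    "model.discount_rate_costs", "model.discount_rate_outcomes",
    "model.horizon_years", "model.max_treatment_years",
    "model.natural_weight_gain", "model.catch_up_years",
    "arms.semaglutide.non_responder_rate",
    "arms.liraglutide.non_responder_rate",
    "risks.conditions.T2D.base_annual_rate"
  )
  base <- vapply(paths, function(p) as.numeric(config_get(cfg, p)), numeric(1))
  tibble::tibble(parameter = paths, path = paths,
                 low = base * (1 - rel_range), high = base * (1 + rel_range))
}

#' One-way deterministic sensitivity analysis with tornado ranking
#'
#' Each item is set to its low and high value in turn (all else at base),
#' the two-arm comparison is rerun, and items are ranked by the absolute
#' ICER span. The top `top` items (default 11) are returned, mirroring the
#' usual tornado presentation.
#'
#' @param cfg an `obemod_config`.
#' @param items tibble from [dsa_default_items()] or with the same columns.
#' @param top number of items to keep after ranking (`Inf` for all).
#' @param intervention,comparator arm names.
#' @return tibble ranked by descending `span`, with `icer_low`, `icer_high`
#'   (ICERs at the item's low/high value) and `icer_base`.
#' @export
run_dsa <- function(cfg = default_config(), items = dsa_default_items(cfg),
                    top = 11, intervention = "semaglutide",
                    comparator = "liraglutide") {
  base_run <- run_comparison(cfg, intervention, comparator)
  base_icer <- base_run$comparison$icer_qaly$value
  one <- function(path, value) {
    run <- run_comparison(config_set(cfg, path, value), intervention,
                          comparator)
    run$comparison$icer_qaly$value
  }
  lo <- hi <- numeric(nrow(items))
  for (i in seq_len(nrow(items))) {
    lo[i] <- tryCatch(one(items$path[i], items$low[i]),
                      error = function(e) stop("DSA item '", items$parameter[i],
                                               "' failed: ", conditionMessage(e),
                                               call. = FALSE))
    hi[i] <- tryCatch(one(items$path[i], items$high[i]),
                      error = function(e) stop("DSA item '", items$parameter[i],
                                               "' failed: ", conditionMessage(e),
                                               call. = FALSE))
  }
  out <- tibble::tibble(parameter = items$parameter, path = items$path,
                        low = items$low, high = items$high,
                        icer_low = lo, icer_high = hi,
                        icer_base = base_icer,
                        span = abs(hi - lo))
  out <- out[order(-out$span), ]
  utils::head(out, top)
}
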