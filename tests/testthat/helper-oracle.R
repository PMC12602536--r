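# Independent reference implementations used as oracles. Deliberately naive:
# explicit element-wise loops, no matrix algebra, no code shared with the
# package internals.

naive_run_cohort <- function(matrices, cycle_lengths, utility, cost, alive,
                             init, discount_costs = 0, discount_outcomes = 0,
                             discount_timing = "mid") {
  S <- length(init)
  v <- init
  t0 <- 0
  lys <- qalys <- costs <- 0
  for (cy in seq_along(cycle_lengths)) {
    len <- cycle_lengths[cy]
    M <- matrices[[cy]]
    v1 <- numeric(S)
    for (j in seq_len(S)) {
      acc <- 0
      for (i in seq_len(S)) acc <- acc + v[i] * M[i, j]
      v1[j] <- acc
    }
    t_disc <- if (discount_timing == "mid") t0 + len / 2 else t0
    dfc <- (1 + discount_costs)^(-t_disc)
    dfo <- (1 + discount_outcomes)^(-t_disc)
    for (s in seq_len(S)) {
      m <- (v[s] + v1[s]) / 2
      if (alive[s]) lys <- lys + dfo * len * m
      qalys <- qalys + dfo * len * m * utility[s, cy]
      costs <- costs + dfc * len * m * cost[s, cy]
    }
    v <- v1
    t0 <- t0 + len
  }
  list(lys = lys, qalys = qalys, costs = costs)
}

# term-by-term polynomial evaluation of the baseline-utility regression
poly_utility_oracle <- function(coefs, age, bmi, heart_circ = 0,
                                hypertension = 0, smoke_current = 0,
                                smoke_previous = 0, prediabetes = 0) {
  terms <- c(
    coefs$intercept,
    coefs$age * age,
    coefs$heart_circ * heart_circ,
    coefs$hypertension * hypertension,
    coefs$smoke_current * smoke_current,
    coefs$smoke_previous * smoke_previous,
    coefs$bmi * bmi,
    coefs$bmi2 * bmi * bmi,
    coefs$bmi3 * bmi * bmi * bmi,
    coefs$prediabetes * prediabetes
  )
  sum(terms)
}

# calendar-walk oracle for total (undiscounted) payer drug spend of a fully
# adherent responder: walks day by day through titration and maintenance
walk_drug_cost <- function(arm, prices, payer_share, years) {
  days <- round(years * 365.25)
  tit_days <- rep(arm$titration$labels, times = arm$titration$weeks * 7)
  total <- 0
  for (d in seq_len(days)) {
    lbl <- if (d <= length(tit_days)) tit_days[d] else arm$maintenance_label
    total <- total + prices[[lbl]] / arm$pack_days
  }
  total * payer_share
}
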