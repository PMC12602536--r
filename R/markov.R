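#' Enumerate the comorbidity state space
#'
#' States are the empty ("no complication") set, every combination of up to
#' `max_combo` of the modeled conditions, and an absorbing death state.
#' Ordering is deterministic: by combination size, then lexicographic in the
#' canonical condition order; death is always last. With the seven modeled
#' complications and triples allowed this yields 1 + 7 + 21 + 35 + 1 = 65
#' states.
#'
#' @param conditions ordered character vector of condition labels.
#' @param max_combo maximum number of coexisting conditions (1 to
#'   `length(conditions)`).
#' @return an `obemod_state_space`: list with `conditions`, `states` (list of
#'   character vectors; `character(0)` for the empty state, `NA` sentinel not
#'   used), `labels`, `n`, `death` (index), `membership` (alive-states x
#'   conditions logical matrix) and `size`.
#' @export
state_space <- function(conditions = model_conditions(), max_combo = 3) {
  stopifnot(max_combo >= 1, max_combo <= length(conditions))
  K <- length(conditions)
  states <- list(character(0))
  for (k in seq_len(max_combo))
    states <- c(states, utils::combn(conditions, k, simplify = FALSE))
  labels <- c("none",
              vapply(states[-1], paste, character(1), collapse = "+"),
              "death")
  n_alive <- length(states)
  membership <- matrix(FALSE, n_alive, K, dimnames = list(NULL, conditions))
  for (i in seq_len(n_alive)) membership[i, states[[i]]] <- TRUE
  structure(list(
    conditions = conditions, states = states, labels = labels,
    n = n_alive + 1L, death = n_alive + 1L, n_alive = n_alive,
    membership = membership, size = rowSums(membership),
    max_combo = max_combo
  ), class = "obemod_state_space")
}

#' @export
print.obemod_state_space <- function(x, ...) {
  cat(sprintf("<obemod_state_space> %d states: none + combinations up to %d of {%s} + death\n",
              x$n, x$max_combo, paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Index of a state by its condition set
#' @param space an `obemod_state_space`.
#' @param conditions character vector of conditions (order-insensitive), or
#'   `"death"`.
#' @return integer state index.
#' @export
state_index <- function(space, conditions) {
  if (identical(conditions, "death")) return(space$death)
  key <- paste(space$conditions[space$conditions %in% conditions], collapse = "+")
  if (length(conditions) == 0) key <- "none"
  idx <- match(key, space$labels)
  if (is.na(idx)) stop("no such state: ", paste(conditions, collapse = "+"),
                       call. = FALSE)
  idx
}

# Precomputed sparse structure of legal single-condition acquisitions:
# entry (row, col, cond) for every alive state below the combination cap and
# every condition it lacks. Aq is the 0/1 acquirable matrix used for the
# competing-risk normalizer.
transition_structure <- function(space) {
  K <- length(space$conditions)
  acq <- !space$membership & space$size < space$max_combo
  rows <- integer(0); cols <- integer(0); cond <- integer(0)
  lab_of <- function(set) if (length(set) == 0) "none" else
    paste(space$conditions[space$conditions %in% set], collapse = "+")
  for (i in seq_len(space$n_alive)) {
    for (k in which(acq[i, ])) {
      tgt <- match(lab_of(c(space$states[[i]], space$conditions[k])), space$labels)
      rows <- c(rows, i); cols <- c(cols, tgt); cond <- c(cond, k)
    }
  }
  list(Aq = acq * 1, rows = rows, cols = cols, cond = cond,
       flat = (cols - 1L) * space$n + rows)
}

#' Assemble one per-cycle transition matrix
#'
#' From each alive state, mortality is allocated first; survivors acquire
#' each absent condition with its competing-risk-normalized cycle
#' probability (the joint-acquisition mass `1 - prod(1 - p_c)` is
#' redistributed proportionally over single acquisitions, so no row adds
#' more than one condition per cycle); states already at the combination cap
#' acquire nothing; the remainder stays put. Death is absorbing.
#'
#' @param space an `obemod_state_space`.
#' @param incidences named per-cycle acquisition probabilities, one per
#'   condition.
#' @param mortality per-cycle death probability: scalar, or vector over
#'   alive states (or over all states; the death entry is ignored).
#' @param struct optional precomputed [transition_structure()] (internal
#'   speed-up for repeated calls).
#' @return row-stochastic `space$n` x `space$n` matrix.
#' @export
build_transition_matrix <- function(space, incidences, mortality,
                                    struct = NULL) {
  st <- struct %||% transition_structure(space)
  S <- space$n
  p <- as.numeric(incidences[space$conditions])
  if (anyNA(p)) stop("incidences must be named for every condition", call. = FALSE)
  stopifnot(all(p >= 0), all(p <= 1))
  pd <- rep_len(as.numeric(mortality), space$n_alive)
  stopifnot(all(pd >= 0), all(pd <= 1))

  lp <- as.vector(st$Aq %*% log1p(-pmin(p, 1 - 1e-15)))
  sp <- as.vector(st$Aq %*% p)
  norm <- ifelse(sp > 0, (1 - exp(lp)) / sp, 0)

  M <- matrix(0, S, S)
  M[st$flat] <- (1 - pd[st$rows]) * norm[st$rows] * p[st$cond]
  acq_tot <- (1 - pd) * norm * sp
  stay <- 1 - pd - acq_tot
  if (any(stay < -1e-9))
    stop("transition allocation exceeds 1 after normalization", call. = FALSE)
  idx <- seq_len(space$n_alive)
  M[cbind(idx, idx)] <- pmax(stay, 0)
  M[cbind(idx, rep(space$death, space$n_alive))] <- pd
  M[space$death, space$death] <- 1
  M
}

#' Discount factor at a point in time
#'
#' `(1 + rate)^(-t)`; in the engine `t` is the mid-cycle time
#' (start + length/2), pairing naturally with half-cycle-corrected rewards.
#'
#' @param t time in years.
#' @param rate annual discount rate (>= 0).
#' @return discount factor(s).
#' @export
discount_factor <- function(t, rate) {
  stopifnot(all(rate >= 0))
  (1 + rate)^(-t)
}

#' Advance a cohort through per-cycle transition matrices
#'
#' The central accumulator: occupancy is advanced cycle by cycle; every
#' reward-rate is valued with the half-cycle correction (cycle length times
#' the average of start and end occupancy) and discounted at the mid-cycle
#' time (or cycle start, by configuration). One-time quantities -- per-alive
#' amounts such as drug acquisition costs, and per-transition amounts such as
#' acute-event costs on entering a condition -- attach at the same cycle and
#' are discounted identically.
#'
#' @param matrices list of row-stochastic matrices, one per cycle.
#' @param cycle_lengths numeric vector of cycle lengths (years).
#' @param utility states x cycles matrix of utility rates (QALY/year).
#' @param cost_components named list of states x cycles matrices of cost
#'   rates (currency/year); a single matrix is accepted and labelled
#'   `"cost"`.
#' @param alive logical vector marking alive states (life-years accrue at
#'   1/year there).
#' @param init initial occupancy vector (sums to 1).
#' @param discount_costs,discount_outcomes annual discount rates.
#' @param discount_timing `"mid"` (default) or `"start"`.
#' @param percycle_cost_components named list of per-cycle vectors: absolute
#'   currency per alive person attached at that cycle (e.g. integrated drug
#'   cost).
#' @param percycle_qaly per-cycle vector of absolute QALY increments per
#'   alive person (negative for event disutilities).
#' @param acquisition_events list of `list(mask, cost, qaly, component)`:
#'   `mask` is a states x states 0/1 matrix selecting transitions that
#'   constitute the event; expected event counts are priced at `cost` and
#'   decrement QALYs by `qaly` (negative), booked to cost component
#'   `component`.
#' @param keep_trace if `TRUE`, return the per-cycle audit trace.
#' @return list with `result` (costs by component and total, `qalys`, `lys`,
#'   and their undiscounted counterparts) and `trace` (tibble or `NULL`).
#' @export
run_cohort <- function(matrices, cycle_lengths, utility, cost_components,
                       alive, init, discount_costs = 0, discount_outcomes = 0,
                       discount_timing = "mid",
                       percycle_cost_components = NULL, percycle_qaly = NULL,
                       acquisition_events = NULL, keep_trace = FALSE) {
  C <- length(cycle_lengths)
  stopifnot(length(matrices) == C)
  S <- length(init)
  if (is.matrix(cost_components)) cost_components <- list(cost = cost_components)
  comp_names <- union(names(cost_components),
                      names(percycle_cost_components %||% list()))
  if (!is.null(acquisition_events))
    comp_names <- union(comp_names,
                        vapply(acquisition_events, `[[`, character(1), "component"))
  costs <- stats::setNames(numeric(length(comp_names)), comp_names)
  costs_undisc <- costs
  qalys <- lys <- qalys_undisc <- lys_undisc <- 0

  v <- init
  t0 <- 0
  tr_rows <- if (keep_trace) vector("list", C) else NULL
  for (c in seq_len(C)) {
    len <- cycle_lengths[c]
    M <- matrices[[c]]
    if (nrow(M) != S) stop("matrix/state dimension mismatch at cycle ", c,
                           call. = FALSE)
    v1 <- as.vector(v %*% M)
    mid <- (v + v1) / 2
    t_disc <- if (discount_timing == "mid") t0 + len / 2 else t0
    dfc <- discount_factor(t_disc, discount_costs)
    dfo <- discount_factor(t_disc, discount_outcomes)
    alive_mid <- sum(mid[alive])

    ly_inc <- len * alive_mid
    q_inc <- len * sum(mid * utility[, c])
    if (!is.null(percycle_qaly)) q_inc <- q_inc + percycle_qaly[c] * alive_mid

    c_inc <- stats::setNames(numeric(length(comp_names)), comp_names)
    for (nm in names(cost_components))
      c_inc[nm] <- c_inc[nm] + len * sum(mid * cost_components[[nm]][, c])
    for (nm in names(percycle_cost_components %||% list()))
      c_inc[nm] <- c_inc[nm] + percycle_cost_components[[nm]][c] * alive_mid
    if (!is.null(acquisition_events)) {
      for (ev in acquisition_events) {
        flux <- sum(v * rowSums(M * ev$mask))
        c_inc[ev$component] <- c_inc[ev$component] + flux * ev$cost
        q_inc <- q_inc + flux * ev$qaly
      }
    }

    lys <- lys + dfo * ly_inc;       lys_undisc <- lys_undisc + ly_inc
    qalys <- qalys + dfo * q_inc;    qalys_undisc <- qalys_undisc + q_inc
    costs <- costs + dfc * c_inc;    costs_undisc <- costs_undisc + c_inc

    if (keep_trace)
      tr_rows[[c]] <- tibble::tibble(
        cycle = c, t_start = t0, cycle_length = len,
        state = seq_len(S), occupancy_start = v, occupancy_end = v1,
        ly_increment = len * mid * alive, discounted_ly = dfo * len * mid * alive)
    v <- v1
    t0 <- t0 + len
  }
  result <- list(
    costs = c(costs, total = sum(costs)),
    qalys = qalys, lys = lys,
    costs_undiscounted = c(costs_undisc, total = sum(costs_undisc)),
    qalys_undiscounted = qalys_undisc, lys_undiscounted = lys_undisc,
    final_occupancy = v
  )
  list(result = result,
       trace = if (keep_trace) do.call(rbind, tr_rows) else NULL)
}
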