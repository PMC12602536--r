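#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' Computed from full-precision increments of the intervention versus the
#' comparator. When the intervention gains QALYs at higher cost the ratio
#' `delta_cost / delta_qaly` is returned; when it gains QALYs at equal or
#' lower cost it is `"dominant"`; when it loses QALYs at equal or higher
#' cost it is `"dominated"`; losing QALYs while saving costs is the
#' south-west trade-off (`"southwest"`, ratio still informative); zero QALY
#' difference is `"undefined"`.
#'
#' @param delta_cost incremental cost (euro).
#' @param delta_qaly incremental effect (QALYs).
#' @return list with `value` (numeric ratio or `NA`) and `label` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"southwest"`, `"undefined"`).
#' @examples
#' icer(1083.37, 0.09)$value    # ~12037 from rounded printed increments
#' icer(-300.65, 0.07)$label    # "dominant"
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0)
    return(list(value = NA_real_, label = "undefined"))
  val <- delta_cost / delta_qaly
  label <- if (delta_qaly > 0 && delta_cost > 0) "icer"
           else if (delta_qaly > 0) "dominant"
           else if (delta_cost >= 0) "dominated"
           else "southwest"
  list(value = val, label = label)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `lambda * delta_qaly - delta_cost`, reported rounded to whole currency
#' units (set `round_to = NULL` for full precision). Positive NMB means the
#' intervention is cost-effective at that threshold.
#'
#' @param delta_cost incremental cost (euro).
#' @param delta_qaly incremental QALYs.
#' @param lambda willingness-to-pay threshold (euro/QALY, >= 0).
#' @param round_to digits for rounding (default 0: whole euro); `NULL`
#'   disables rounding.
#' @return NMB in euro.
#' @examples
#' nmb(1083.37, 0.09, 27117)  # 1357
#' nmb(1083.37, 0.09, 30000)  # 1617
#' @export
nmb <- function(delta_cost, delta_qaly, lambda, round_to = 0) {
  stopifnot(all(lambda >= 0))
  out <- lambda * delta_qaly - delta_cost
  if (!is.null(round_to)) out <- round(out, round_to)
  out
}

#' Cost-effectiveness plane quadrant
#'
#' `NE`: more effective, more costly; `SE`: more effective, cost-saving
#' (dominant); `NW`: less-or-equally effective, more costly; `SW`:
#' otherwise. Boundary conventions: `delta_cost = 0` with a QALY gain falls
#' in `SE`; `delta_qaly = 0` falls in `NW`.
#'
#' @param delta_cost incremental cost(s).
#' @param delta_qaly incremental QALY(s).
#' @return character vector of quadrant labels.
#' @export
ce_quadrant <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly > 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_cost >= 0, "NW", "SW"))
}

#' Compare two arm results
#'
#' Computes incremental costs (total and by component), QALYs and LYs, the
#' ICERs per QALY and per LY, NMB at each willingness-to-pay threshold, and
#' the cost-effectiveness plane quadrant, for an intervention versus a
#' comparator.
#'
#' @param intervention,comparator arm results as returned in
#'   `run_arm(...)$result` (lists with `costs`, `qalys`, `lys`).
#' @param wtp_thresholds numeric vector of thresholds (euro/QALY).
#' @return an `obemod_comparison`: list with `delta_cost`,
#'   `delta_cost_components`, `delta_qaly`, `delta_ly`, `icer_qaly` (list
#'   value/label), `icer_ly`, `nmb` (named by threshold), `quadrant`.
#' @export
compare_arms <- function(intervention, comparator,
                         wtp_thresholds = c(27117, 30000, 34000)) {
  d_cost <- unname(intervention$costs["total"] - comparator$costs["total"])
  comp <- setdiff(names(intervention$costs), "total")
  d_comp <- intervention$costs[comp] - comparator$costs[comp]
  d_q <- intervention$qalys - comparator$qalys
  d_ly <- intervention$lys - comparator$lys
  structure(list(
    delta_cost = d_cost, delta_cost_components = d_comp,
    delta_qaly = d_q, delta_ly = d_ly,
    icer_qaly = icer(d_cost, d_q), icer_ly = icer(d_cost, d_ly),
    nmb = stats::setNames(nmb(d_cost, d_q, wtp_thresholds),
                          paste0("wtp_", wtp_thresholds)),
    quadrant = ce_quadrant(d_cost, d_q)
  ), class = "obemod_comparison")
}

#' @export
print.obemod_comparison <- function(x, ...) {
  cat("<obemod_comparison>\n")
  cat(sprintf("  incremental cost:  %10.2f EUR\n", x$delta_cost))
  for (nm in names(x$delta_cost_components))
    cat(sprintf("    %-11s %10.2f\n", nm, x$delta_cost_components[nm]))
  cat(sprintf("  incremental QALYs: %10.4f   incremental LYs: %.4f\n",
              x$delta_qaly, x$delta_ly))
  if (x$icer_qaly$label == "icer")
    cat(sprintf("  ICER: %.0f EUR/QALY (%s quadrant)\n",
                x$icer_qaly$value, x$quadrant))
  else cat(sprintf("  ICER: %s (%s quadrant)\n", x$icer_qaly$label, x$quadrant))
  for (nm in names(x$nmb)) cat(sprintf("  NMB %s: %.0f EUR\n", nm, x$nmb[nm]))
  invisible(x)
}

#' Results formatted as a base-case summary table
#'
#' @param intervention,comparator arm results (`run_arm(...)$result`).
#' @param comparison an `obemod_comparison` from [compare_arms()].
#' @param arm_names character(2) display names.
#' @return tibble shaped like a published base-case table: one row per cost
#'   component, totals, QALYs, LYs, ICERs and NMBs.
#' @export
comparison_table <- function(intervention, comparator, comparison,
                             arm_names = c("intervention", "comparator")) {
  gc <- function(x, nm) unname(x$costs[nm])
  out <- tibble::tibble(
    parameter = c("Discounted total direct medical costs", "Treatment costs",
                  "Monitoring costs", "Complication state costs",
                  "Complication event costs", "Discounted QALYs",
                  "Discounted LYs", "ICER (EUR/QALY)", "ICER (EUR/LY)"),
    a = c(gc(intervention, "total"), gc(intervention, "treatment"),
          gc(intervention, "monitoring"), gc(intervention, "state"),
          gc(intervention, "event"), intervention$qalys, intervention$lys,
          NA_real_, NA_real_),
    b = c(gc(comparator, "total"), gc(comparator, "treatment"),
          gc(comparator, "monitoring"), gc(comparator, "state"),
          gc(comparator, "event"), comparator$qalys, comparator$lys,
          NA_real_, NA_real_),
    incremental = c(comparison$delta_cost,
                    unname(comparison$delta_cost_components[
                      c("treatment", "monitoring", "state", "event")]),
                    comparison$delta_qaly, comparison$delta_ly,
                    comparison$icer_qaly$value, comparison$icer_ly$value)
  )
  names(out)[2:3] <- arm_names
  out
}
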