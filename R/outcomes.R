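#' Per-cycle discount factor
#'
#' `(1 + rate)^(-cycle * cycle_days / 365.25)`: cycle 0 is undiscounted and
#' the factor decreases with the cycle index.
#'
#' @param cycle Cycle index (vectorized).
#' @param annual_rate Annual discount rate, non-negative.
#' @param cycle_days Cycle length in days.
#' @return Discount factor in `(0, 1]`.
#' @examples
#' discount_factor(26, 0.05, 14)
#' @export
discount_factor <- function(cycle, annual_rate, cycle_days) {
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle * cycle_days / 365.25)
}

#' Per-cycle cost and QALY rewards of a trace
#'
#' Costs: the controlled-state annual cost prorated to the cycle, per-episode
#' costs applied to each event channel's incidence, and the drug cost
#' (quoted per 4 weeks) prorated to the cycle for the on-treatment alive
#' mass. QALYs: alive person-time at the controlled-state utility minus one
#' cycle's worth of each event's utility decrement, prorated by
#' `cycle_days / 365.25`. A cycle whose computed QALY would be negative is
#' clamped to 0 with a warning.
#'
#' @param trace A `cohort_trace` (or any data frame with its columns).
#' @param params A `parameter_set`.
#' @param strategy Strategy label (carried through; the drug cost is driven
#'   by the trace's `frac_on_treatment`, so comparator traces incur none).
#' @return A data frame with per-cycle `cost` and `qaly` columns.
#' @export
cycle_rewards <- function(trace, params, strategy = attr(trace, "strategy")) {
  cd <- params$econ$cycle_days
  yr <- cd / 365.25
  cs <- params$costs
  u <- params$utilities
  cost <- trace$alive * cs$controlled_state_annual$base * yr +
    trace$inc_ocs * cs$ocs_burst_per_episode$base +
    trace$inc_ed * cs$ed_visit_per_episode$base +
    trace$inc_hosp * cs$hospitalization_per_episode$base +
    trace$frac_on_treatment * trace$alive * cs$drug_per_4wk$base * cd / 28
  qaly <- (trace$alive * u$controlled$base -
             trace$inc_ocs * u$decrement_ocs$base -
             trace$inc_ed * u$decrement_ed$base -
             trace$inc_hosp * u$decrement_hosp$base) * yr
  if (any(qaly < 0)) {
    warning("negative per-cycle QALY clamped to 0 in ", sum(qaly < 0),
            " cycle(s)", call. = FALSE)
    qaly <- pmax(qaly, 0)
  }
  data.frame(cycle = trace$cycle, cost = cost, qaly = qaly)
}

half_cycle_weights <- function(n) {
  if (n == 1L) return(0.5)
  c(0.5, rep(1, n - 2L), 0.5)
}

#' Discounted lifetime totals for one strategy
#'
#' Accumulates per-cycle rewards with half-cycle correction (trapezoidal end
#' weights 1/2, 1, ..., 1, 1/2) and per-cycle discounting; both discounted
#' and undiscounted totals are returned.
#'
#' @param trace A `cohort_trace`.
#' @param params A `parameter_set`.
#' @param strategy Strategy label.
#' @return A `strategy_result` list: `strategy`, `discounted_cost`,
#'   `discounted_qaly`, `undiscounted_cost`, `undiscounted_qaly`, and the
#'   per-cycle reward streams.
#' @export
accumulate_strategy <- function(trace, params,
                                strategy = attr(trace, "strategy")) {
  stopifnot(nrow(trace) >= 1L)
  rw <- cycle_rewards(trace, params, strategy)
  w <- half_cycle_weights(nrow(trace))
  disc <- discount_factor(trace$cycle,
                          params$econ$annual_discount_rate$base,
                          params$econ$cycle_days)
  structure(list(
    strategy = strategy,
    discounted_cost  = sum(w * disc * rw$cost),
    discounted_qaly  = sum(w * disc * rw$qaly),
    undiscounted_cost = sum(w * rw$cost),
    undiscounted_qaly = sum(w * rw$qaly),
    cycle_rewards = rw),
    class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result: %s>\n", x$strategy))
  cat(sprintf("  discounted   cost %10.2f US$   QALY %8.4f\n",
              x$discounted_cost, x$discounted_qaly))
  cat(sprintf("  undiscounted cost %10.2f US$   QALY %8.4f\n",
              x$undiscounted_cost, x$undiscounted_qaly))
  invisible(x)
}

#' Incremental cost-effectiveness ratio with quadrant label
#'
#' Returns the ratio when the QALY difference is nonzero, otherwise a label;
#' always labels the cost-effectiveness-plane quadrant. Note that a negative
#' ICER is ambiguous on its own — the quadrant disambiguates dominance from
#' a losing trade-off.
#'
#' @param delta_cost Incremental cost (add-on minus comparator), US$.
#' @param delta_qaly Incremental QALYs.
#' @return A list with `icer` (number or `NA`), `label`, `quadrant`.
#' @examples
#' icer(-4.65, 0.0018)
#' @export
icer <- function(delta_cost, delta_qaly) {
  quadrant <- if (delta_qaly > 0 && delta_cost < 0) {
    "dominant (SE: cheaper, more effective)"
  } else if (delta_qaly < 0 && delta_cost > 0) {
    "dominated (NW: costlier, less effective)"
  } else if (delta_qaly > 0 && delta_cost >= 0) {
    "trade-off (NE: costlier, more effective)"
  } else if (delta_qaly < 0 && delta_cost <= 0) {
    "trade-off (SW: cheaper, less effective)"
  } else {
    "no QALY difference"
  }
  if (delta_qaly != 0) {
    list(icer = delta_cost / delta_qaly, label = "ratio", quadrant = quadrant)
  } else if (delta_cost == 0) {
    list(icer = NA_real_, label = "equivalent", quadrant = quadrant)
  } else {
    list(icer = NA_real_, label = "undefined (cost-only difference)",
         quadrant = quadrant)
  }
}

#' Net monetary benefit
#'
#' `NMB = QALYs * wtp - cost`; [nb_effects()] is the companion on the
#' effects scale, `NMB / wtp`.
#'
#' @param qaly QALYs (vectorized).
#' @param cost Cost in US$ (vectorized).
#' @param wtp Willingness-to-pay threshold, US$ per QALY, positive.
#' @return Net monetary benefit in US$.
#' @examples
#' nmb(0.1732, 96, 5180)
#' @export
nmb <- function(qaly, cost, wtp) {
  if (any(wtp <= 0)) stop("wtp must be > 0", call. = FALSE)
  qaly * wtp - cost
}

#' @rdname nmb
#' @export
nb_effects <- function(qaly, cost, wtp) {
  nmb(qaly, cost, wtp) / wtp
}

#' Deterministic head-to-head comparison of the two strategies
#'
#' Runs both cohorts with the same parameter set, accumulates discounted
#' totals, and assembles the incremental block (delta cost, delta QALYs,
#' ICER with quadrant, per-strategy and incremental net monetary benefit,
#' and the effects-scale net benefit).
#'
#' @inheritParams run_cohort
#' @param wtp Willingness-to-pay; defaults to the parameter set's value.
#' @return An `incremental_result` list.
#' @examples
#' lt <- synthetic_life_table()
#' compare_strategies(table1_fixture(), scenario_spec(), lt)
#' @export
compare_strategies <- function(params, scenario = scenario_spec(),
                               life_table = synthetic_life_table(),
                               wtp = params$econ$wtp_per_qaly) {
  comp <- accumulate_strategy(
    run_cohort(params, "comparator", scenario, life_table), params,
    "comparator")
  addon <- accumulate_strategy(
    run_cohort(params, "add_on", scenario, life_table), params, "add_on")
  delta_cost <- addon$discounted_cost - comp$discounted_cost
  delta_qaly <- addon$discounted_qaly - comp$discounted_qaly
  nmb_comp <- nmb(comp$discounted_qaly, comp$discounted_cost, wtp)
  nmb_addon <- nmb(addon$discounted_qaly, addon$discounted_cost, wtp)
  structure(list(
    comparator = comp, add_on = addon,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icer = icer(delta_cost, delta_qaly),
    wtp = wtp,
    nmb_comparator = nmb_comp, nmb_add_on = nmb_addon,
    nmb_incremental = nmb_addon - nmb_comp,
    nb_effects_comparator = nmb_comp / wtp,
    nb_effects_add_on = nmb_addon / wtp),
    class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> add-on vs comparator\n")
  cat(sprintf("  delta cost %9.3f US$   delta QALY %9.5f\n",
              x$delta_cost, x$delta_qaly))
  if (!is.na(x$icer$icer)) {
    cat(sprintf("  ICER %10.2f US$/QALY   [%s]\n", x$icer$icer,
                x$icer$quadrant))
  } else {
    cat(sprintf("  ICER: %s [%s]\n", x$icer$label, x$icer$quadrant))
  }
  cat(sprintf("  NMB at %g US$/QALY: comparator %.2f, add-on %.2f, ",
              x$wtp, x$nmb_comparator, x$nmb_add_on))
  cat(sprintf("incremental %.3f\n", x$nmb_incremental))
  invisible(x)
}
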