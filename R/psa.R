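#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Repeatedly samples one joint parameter set per draw (common random
#' parameters: the same sampled set drives both strategies, so incremental
#' contrasts are within-draw), runs both cohorts deterministically, and
#' records discounted lifetime cost and QALYs per strategy. Fully
#' reproducible from `seed`.
#'
#' @inheritParams run_cohort
#' @param n_runs Number of PSA draws (default 10,000).
#' @param seed Integer seed for the draw stream (`NULL` leaves the RNG state
#'   untouched).
#' @return A `psa_draws` data frame: `draw`, `cost_comparator`,
#'   `qaly_comparator`, `cost_addon`, `qaly_addon`, `delta_cost`,
#'   `delta_qaly`; attributes carry `wtp`, `seed`, `n_runs`.
#' @examples
#' lt <- synthetic_life_table()
#' d <- run_psa(table1_fixture(), scenario_spec(horizon = 52), lt,
#'              n_runs = 25, seed = 1)
#' colMeans(d[, c("delta_cost", "delta_qaly")])
#' @export
run_psa <- function(params, scenario = scenario_spec(),
                    life_table = synthetic_life_table(),
                    n_runs = 10000L, seed = NULL) {
  stopifnot(n_runs >= 1L)
  # distribution construction errors surface here, before any draw
  invisible(parameter_distributions(params))
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_parameters(params, n_runs)
  out <- matrix(NA_real_, nrow = n_runs, ncol = 4L)
  for (i in seq_len(n_runs)) {
    p_i <- apply_draw(params, draws[i, ])
    res <- compare_strategies(p_i, scenario, life_table,
                              wtp = params$econ$wtp_per_qaly)
    out[i, ] <- c(res$comparator$discounted_cost,
                  res$comparator$discounted_qaly,
                  res$add_on$discounted_cost,
                  res$add_on$discounted_qaly)
  }
  res <- data.frame(draw = seq_len(n_runs),
                    cost_comparator = out[, 1], qaly_comparator = out[, 2],
                    cost_addon = out[, 3], qaly_addon = out[, 4])
  res$delta_cost <- res$cost_addon - res$cost_comparator
  res$delta_qaly <- res$qaly_addon - res$qaly_comparator
  attr(res, "wtp") <- params$econ$wtp_per_qaly
  attr(res, "seed") <- seed
  attr(res, "n_runs") <- n_runs
  class(res) <- c("psa_draws", "data.frame")
  res
}

#' Summary statistics of a PSA draw set
#'
#' Mean incremental cost and effect, the ICER of the means, 2.5th/97.5th
#' empirical centiles (linear-interpolation quantiles), decision
#' probabilities (cost saving, more effective, cost-effective at `wtp`), and
#' per-strategy mean cost/QALY with expected net monetary benefit and its
#' credible interval. The expected NMB is computed as
#' `mean(QALY) * wtp - mean(cost)` (identical, by linearity, to the mean of
#' per-draw NMBs).
#'
#' @param draws A `psa_draws` data frame.
#' @param wtp Willingness-to-pay threshold, US$ per QALY.
#' @return A `psa_summary` list.
#' @export
summarize_psa <- function(draws, wtp = attr(draws, "wtp")) {
  stopifnot(nrow(draws) >= 2L)
  q <- function(x) unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  nmb_comp <- nmb(draws$qaly_comparator, draws$cost_comparator, wtp)
  nmb_addon <- nmb(draws$qaly_addon, draws$cost_addon, wtp)
  nmb_inc <- nmb_addon - nmb_comp
  ci_dc <- q(draws$delta_cost); ci_de <- q(draws$delta_qaly)
  ci_nmb_comp <- q(nmb_comp); ci_nmb_addon <- q(nmb_addon)
  mean_dc <- mean(draws$delta_cost); mean_de <- mean(draws$delta_qaly)
  structure(list(
    n_runs = nrow(draws), wtp = wtp,
    mean_delta_cost = mean_dc, mean_delta_qaly = mean_de,
    icer_of_means = icer(mean_dc, mean_de),
    ci_delta_cost = ci_dc, ci_delta_qaly = ci_de,
    p_cost_saving = mean(draws$delta_cost < 0),
    p_more_effective = mean(draws$delta_qaly > 0),
    # same expression the CEAC uses, so the two agree exactly at the threshold
    p_cost_effective = mean(wtp * draws$delta_qaly - draws$delta_cost > 0),
    mean_cost_comparator = mean(draws$cost_comparator),
    mean_qaly_comparator = mean(draws$qaly_comparator),
    mean_cost_addon = mean(draws$cost_addon),
    mean_qaly_addon = mean(draws$qaly_addon),
    nmb_comparator = mean(draws$qaly_comparator) * wtp -
      mean(draws$cost_comparator),
    nmb_addon = mean(draws$qaly_addon) * wtp - mean(draws$cost_addon),
    ci_nmb_comparator = ci_nmb_comp,
    ci_nmb_addon = ci_nmb_addon,
    nb_effects_comparator = (mean(draws$qaly_comparator) * wtp -
                               mean(draws$cost_comparator)) / wtp,
    nb_effects_addon = (mean(draws$qaly_addon) * wtp -
                          mean(draws$cost_addon)) / wtp,
    ci_nb_effects_comparator = ci_nmb_comp / wtp,
    ci_nb_effects_addon = ci_nmb_addon / wtp),
    class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("<psa_summary> %d runs at WTP %g US$/QALY\n", x$n_runs, x$wtp))
  cat(sprintf("  mean dC %.3f [%.3f, %.3f]  mean dE %.5f [%.5f, %.5f]\n",
              x$mean_delta_cost, x$ci_delta_cost[1], x$ci_delta_cost[2],
              x$mean_delta_qaly, x$ci_delta_qaly[1], x$ci_delta_qaly[2]))
  ic <- x$icer_of_means
  cat(sprintf("  ICER of means %s [%s]\n",
              if (is.na(ic$icer)) ic$label else sprintf("%.2f", ic$icer),
              ic$quadrant))
  cat(sprintf("  P(cost saving) %.3f  P(more effective) %.3f  P(CE) %.3f\n",
              x$p_cost_saving, x$p_more_effective, x$p_cost_effective))
  cat(sprintf("  expected NMB: comparator %.2f, add-on %.2f\n",
              x$nmb_comparator, x$nmb_addon))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability the add-on strategy is cost-effective at each threshold:
#' the fraction of draws with positive incremental net benefit,
#' `lambda * dE - dC > 0`. At `lambda = 0` this is P(cost saving); as
#' `lambda` grows it tends to P(more effective).
#'
#' @param draws A `psa_draws` data frame.
#' @param lambdas Threshold grid (default 0 to 15,540 = 3x the base
#'   willingness-to-pay, 101 points).
#' @return A `ceac_curve` data frame with columns `lambda`, `probability`.
#' @export
ceac <- function(draws, lambdas = seq(0, 15540, length.out = 101)) {
  stopifnot(all(lambdas >= 0))
  prob <- vapply(lambdas,
                 function(l) mean(l * draws$delta_qaly - draws$delta_cost > 0),
                 numeric(1))
  structure(data.frame(lambda = lambdas, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

dsa_parameter_paths <- function() {
  c("costs.drug_per_4wk", "costs.controlled_state_annual",
    "costs.ocs_burst_per_episode", "costs.ed_visit_per_episode",
    "costs.hospitalization_per_episode",
    "utilities.controlled", "utilities.decrement_ocs",
    "utilities.decrement_ed", "utilities.decrement_hosp",
    "effect.rr_exacerbation", "events.exacerbation_annual_rate",
    "adherence.discontinuation", "econ.annual_discount_rate")
}

get_path <- function(params, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[p[1]]][[p[2]]]
}

set_path_base <- function(params, path, value) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[p[1]]][[p[2]]]$base <- value
  params
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each ranged parameter in turn to its lower and then upper bound (all
#' others at base case), reruns both strategies deterministically, and
#' records the incremental net monetary benefit and ICER at each endpoint.
#' Rows are ordered by bar width, `|NMB(high) - NMB(low)|`, descending —
#' the tornado ordering.
#'
#' @inheritParams run_cohort
#' @param wtp Willingness-to-pay threshold.
#' @return A `dsa_result` data frame: `parameter`, `lower`, `upper`,
#'   `nmb_low`, `nmb_high`, `icer_low`, `icer_high`, `width`; the base-case
#'   incremental NMB is attached as attribute `base_nmb`.
#' @export
one_way_dsa <- function(params, scenario = scenario_spec(),
                        life_table = synthetic_life_table(),
                        wtp = params$econ$wtp_per_qaly) {
  base <- compare_strategies(params, scenario, life_table, wtp)
  rows <- lapply(dsa_parameter_paths(), function(path) {
    pr <- get_path(params, path)
    at <- function(v) {
      compare_strategies(set_path_base(params, path, v), scenario,
                         life_table, wtp)
    }
    lo <- at(pr$lower); hi <- at(pr$upper)
    data.frame(parameter = path, lower = pr$lower, upper = pr$upper,
               nmb_low = lo$nmb_incremental, nmb_high = hi$nmb_incremental,
               icer_low = lo$icer$icer, icer_high = hi$icer$icer,
               width = abs(hi$nmb_incremental - lo$nmb_incremental),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base$nmb_incremental
  attr(out, "wtp") <- wtp
  class(out) <- c("dsa_result", "data.frame")
  out
}

#' Export PSA artifacts as CSV
#'
#' `write_psa_csv` writes the per-draw results (including incremental NMB at
#' the draw set's threshold); `write_ce_plane_csv` writes the
#' cost-effectiveness plane points `(delta_qaly, delta_cost)`;
#' `write_ceac_csv` writes a CEAC grid.
#'
#' @param draws A `psa_draws` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(draws, path) {
  wtp <- attr(draws, "wtp")
  out <- as.data.frame(draws)
  out$nmb_incremental <- nmb(out$delta_qaly, out$delta_cost, wtp) # dE*wtp - dC
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @export
write_ce_plane_csv <- function(draws, path) {
  utils::write.csv(data.frame(delta_qaly = draws$delta_qaly,
                              delta_cost = draws$delta_cost),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @param curve A `ceac_curve` data frame.
#' @export
write_ceac_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
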