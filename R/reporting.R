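#' Manifest of every assumption in force for a run
#'
#' Records the package version, seed, a digest of the parameter set, and the
#' declared modelling defaults (event split, case fatality, adherence
#' interpretation, PSA size) so that a report can be reproduced bit-for-bit
#' from the manifest plus the parameter file.
#'
#' @param params A `parameter_set`.
#' @param scenario A `scenario_spec`.
#' @param n_runs PSA size used.
#' @param seed Seed used.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(params, scenario, n_runs, seed) {
  structure(list(
    package = "tiocue",
    version = as.character(utils::packageVersion("tiocue")),
    seed = seed,
    n_runs = n_runs,
    parameter_digest = parameter_digest(params),
    start_age = scenario$start_age,
    prop_female = scenario$prop_female,
    horizon = scenario$horizon,
    assumptions = list(
      event_split = c(ocs = params$events$split_ocs,
                      ed = params$events$split_ed,
                      hosp = params$events$split_hosp),
      asthma_case_fatality_hosp = params$events$asthma_case_fatality_hosp,
      discontinuation = params$adherence$discontinuation$base,
      waning_cycle = params$adherence$waning_cycle,
      cycle_days = params$econ$cycle_days,
      range_to_sd = "95% interval: sd = (upper - lower) / 3.92",
      half_cycle = "trapezoidal end weights (1/2, 1, ..., 1, 1/2)",
      quantiles = "empirical, linear interpolation (type 7)")),
    class = "run_manifest")
}

# stable digest of the parameter content (canonical JSON -> md5)
parameter_digest <- function(params) {
  txt <- jsonlite::toJSON(unclass_deep(params), digits = NA, auto_unbox = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Assemble the summary report
#'
#' Builds the two summary tables (cost-effectiveness statistics; absolute
#' net-benefit statistics) from a PSA summary and the base-case incremental
#' block, together with the run manifest. Internal consistency is enforced
#' before anything is rendered: the summary's expected net benefits must
#' equal `mean QALY * wtp - mean cost`, the base block and summary must use
#' the same threshold, and (when the draws are supplied) the reported
#' probability of cost-effectiveness must equal the acceptability curve at
#' the threshold. Any inconsistency is a hard error — an inconsistent report
#' is never emitted.
#'
#' @param summary A `psa_summary`.
#' @param base An `incremental_result` (base case).
#' @param manifest A `run_manifest`.
#' @param draws Optional `psa_draws` for the CEAC-at-threshold cross-check.
#' @return A `model_report` list with elements `ce_statistics`,
#'   `net_benefit`, `base_case`, `manifest`.
#' @export
render_report <- function(summary, base, manifest, draws = NULL) {
  if (!isTRUE(all.equal(summary$wtp, base$wtp))) {
    stop("inconsistent report inputs: summary WTP ", summary$wtp,
         " != base-case WTP ", base$wtp, call. = FALSE)
  }
  nmb_check <- function(reported, q, c) {
    if (abs(reported - (q * summary$wtp - c)) > 1e-9) {
      stop("internal inconsistency: expected net benefit does not equal ",
           "mean QALY * WTP - mean cost", call. = FALSE)
    }
  }
  nmb_check(summary$nmb_comparator, summary$mean_qaly_comparator,
            summary$mean_cost_comparator)
  nmb_check(summary$nmb_addon, summary$mean_qaly_addon,
            summary$mean_cost_addon)
  if (!is.null(draws)) {
    at_wtp <- ceac(draws, summary$wtp)$probability
    if (at_wtp != summary$p_cost_effective) {
      stop("internal inconsistency: CEAC at the threshold (", at_wtp,
           ") does not match the reported probability of cost-effectiveness (",
           summary$p_cost_effective, ")", call. = FALSE)
    }
  }
  ic <- summary$icer_of_means
  ce_statistics <- list(
    "Threshold (US$ per QALY)" = summary$wtp,
    "Intervention" = "Tiotropium + ICS + LABA",
    "Comparator" = "ICS + LABA",
    "Number of PSA runs" = summary$n_runs,
    "Mean incremental effect per person (QALY)" = summary$mean_delta_qaly,
    "Mean incremental cost per person (US$)" = summary$mean_delta_cost,
    "ICER estimate (US$ per QALY)" =
      if (is.na(ic$icer)) ic$label else ic$icer,
    "ICER quadrant" = ic$quadrant,
    "2.5th centile for inc. effects (QALY)" = summary$ci_delta_qaly[1],
    "97.5th centile for inc. effects (QALY)" = summary$ci_delta_qaly[2],
    "2.5th centile for inc. costs (US$)" = summary$ci_delta_cost[1],
    "97.5th centile for inc. costs (US$)" = summary$ci_delta_cost[2],
    "Probability intervention is cost saving" = summary$p_cost_saving,
    "Probability intervention provides more benefit" =
      summary$p_more_effective,
    "Probability that intervention is cost-effective against comparator" =
      summary$p_cost_effective)
  net_benefit <- list(
    "Mean discounted lifetime QALYs" =
      c(comparator = summary$mean_qaly_comparator,
        add_on = summary$mean_qaly_addon),
    "Mean discounted lifetime costs (US$)" =
      c(comparator = summary$mean_cost_comparator,
        add_on = summary$mean_cost_addon),
    "Expected net benefit (US$)" =
      c(comparator = summary$nmb_comparator, add_on = summary$nmb_addon),
    "95% lower CI (on costs scale)" =
      c(comparator = summary$ci_nmb_comparator[1],
        add_on = summary$ci_nmb_addon[1]),
    "95% upper CI (on costs scale)" =
      c(comparator = summary$ci_nmb_comparator[2],
        add_on = summary$ci_nmb_addon[2]),
    "Expected net benefit on effects scale (QALY)" =
      c(comparator = summary$nb_effects_comparator,
        add_on = summary$nb_effects_addon),
    "95% lower CI (on effects scale)" =
      c(comparator = summary$ci_nb_effects_comparator[1],
        add_on = summary$ci_nb_effects_addon[1]),
    "95% upper CI (on effects scale)" =
      c(comparator = summary$ci_nb_effects_comparator[2],
        add_on = summary$ci_nb_effects_addon[2]))
  base_case <- list(
    delta_cost = base$delta_cost, delta_qaly = base$delta_qaly,
    icer = base$icer, nmb_incremental = base$nmb_incremental,
    nmb_comparator = base$nmb_comparator, nmb_add_on = base$nmb_add_on)
  structure(list(ce_statistics = ce_statistics, net_benefit = net_benefit,
                 base_case = base_case, manifest = unclass(manifest)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("== Cost-effectiveness statistics ==\n")
  for (nm in names(x$ce_statistics)) {
    v <- x$ce_statistics[[nm]]
    cat(sprintf("  %-62s %s\n", nm,
                if (is.numeric(v)) format(signif(v, 6)) else v))
  }
  cat("== Absolute net benefit ==\n")
  for (nm in names(x$net_benefit)) {
    v <- x$net_benefit[[nm]]
    cat(sprintf("  %-46s comparator %12.4f   add-on %12.4f\n", nm,
                v["comparator"], v["add_on"]))
  }
  invisible(x)
}

#' Write a report (or any result list) as JSON
#'
#' @param x A `model_report`, `psa_summary`, or plain list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
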