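#' Convert an annual event rate to a per-cycle probability
#'
#' Constant-hazard conversion `1 - exp(-rate * cycle_days / 365.25)`;
#' monotone increasing in the rate, 0 maps to 0.
#'
#' @param annual_rate Events per person-year, non-negative (vectorized).
#' @param cycle_days Cycle length in days.
#' @return Per-cycle event probability.
#' @examples
#' rate_to_cycle_probability(1.14, 14)
#' @export
rate_to_cycle_probability <- function(annual_rate, cycle_days) {
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0", call. = FALSE)
  if (cycle_days <= 0) stop("cycle_days must be positive", call. = FALSE)
  1 - exp(-annual_rate * cycle_days / 365.25)
}

#' @rdname rate_to_cycle_probability
#' @param p Per-cycle probability in `[0, 1)` to convert back to an annual
#'   rate.
#' @export
cycle_probability_to_rate <- function(p, cycle_days) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  -log(1 - p) * 365.25 / cycle_days
}

#' Apply a relative risk to an event rate
#'
#' The treatment effect acts multiplicatively on the rate scale, before the
#' conversion to a per-cycle probability.
#'
#' @param annual_rate Events per person-year, non-negative.
#' @param rr Relative risk, positive.
#' @return The treated annual rate.
#' @export
apply_relative_risk <- function(annual_rate, rr) {
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0", call. = FALSE)
  if (any(rr <= 0)) stop("rr must be > 0", call. = FALSE)
  annual_rate * rr
}

# per-cycle event-channel probabilities for one treatment regime;
# normalized (with a warning) in the unusual case their sum exceeds 1
event_channel_probs <- function(params, on_treatment) {
  rate <- params$events$exacerbation_annual_rate$base
  if (on_treatment) {
    rate <- apply_relative_risk(rate, params$effect$rr_exacerbation$base)
  }
  cd <- params$econ$cycle_days
  p <- c(
    ocs  = rate_to_cycle_probability(params$events$split_ocs * rate, cd),
    ed   = rate_to_cycle_probability(params$events$split_ed * rate, cd),
    hosp = rate_to_cycle_probability(params$events$split_hosp * rate, cd))
  if (sum(p) > 1) {
    warning("event-channel probabilities sum to ", signif(sum(p), 4),
            " > 1; normalized", call. = FALSE)
    p <- p / sum(p)
  }
  p
}

#' Per-cycle transition structure at a given age
#'
#' Assembles the five transition quantities governing one model cycle:
#' the three exacerbation-channel probabilities (OCS burst, ED visit,
#' hospitalization), the background (all-cause) death probability from the
#' life table, and the asthma case fatality applied to the hospitalization
#' channel. Competing risks are resolved by applying background death first;
#' event probabilities then apply to the survivors, with at most one
#' exacerbation per cycle.
#'
#' @param params A `parameter_set`.
#' @param on_treatment Logical: does the relative risk apply?
#' @param age Age in years (looked up by completed integer age).
#' @param life_table A `life_table`.
#' @param prop_female Female proportion for sex-specific tables.
#' @return A `cycle_transition` list with fields `p_event_ocs`,
#'   `p_event_ed`, `p_event_hosp`, `p_death_background`, `p_death_asthma`.
#' @export
build_cycle_transition <- function(params, on_treatment, age, life_table,
                                   prop_female = 0.5) {
  stream <- qx_stream(life_table, prop_female)
  if (floor(age) < stream$min_age) {
    stop("age ", age, " below the life-table range", call. = FALSE)
  }
  p <- event_channel_probs(params, on_treatment)
  tr <- list(
    p_event_ocs  = unname(p["ocs"]),
    p_event_ed   = unname(p["ed"]),
    p_event_hosp = unname(p["hosp"]),
    p_death_background = annual_q_to_cycle_q(qx_at_age(stream, age),
                                             params$econ$cycle_days),
    p_death_asthma = params$events$asthma_case_fatality_hosp)
  if (sum(p) > 1 + 1e-12) {
    stop("event probabilities sum beyond 1 after adjustment", call. = FALSE)
  }
  structure(tr, class = "cycle_transition")
}

# ---- internal vectorized engine ------------------------------------------
#
# Boundaries k = 0..K. alive[k+1] = alive[k] * (1 - p_bg[k]) *
# (1 - p_hosp[k] * cfr): background death first, then (for survivors) at
# most one exacerbation event, hospitalization carrying the asthma case
# fatality. Event incidence at boundary k is the alive mass surviving
# background death times the channel probability.
cohort_core <- function(p_bg, p_ocs, p_ed, p_hosp, cfr) {
  K1 <- length(p_bg)  # number of boundaries (K + 1)
  s <- (1 - p_bg) * (1 - p_hosp * cfr)
  alive <- c(1, cumprod(s[-K1]))
  surv <- alive * (1 - p_bg)
  list(alive = alive,
       dead = 1 - alive,
       inc_ocs = surv * p_ocs,
       inc_ed = surv * p_ed,
       inc_hosp = surv * p_hosp)
}

# boundary ages and number of boundaries for a scenario
plan_cycles <- function(params, scenario, stream) {
  cd <- params$econ$cycle_days
  if (identical(scenario$horizon, "lifetime")) {
    # run until the terminal life-table age has been applied once
    K <- ceiling((stream$max_age - scenario$start_age) * 365.25 / cd) + 1L
  } else {
    K <- as.integer(scenario$horizon)
  }
  ages <- scenario$start_age + (0:K) * cd / 365.25
  list(K = K, ages = ages,
       p_bg = annual_q_to_cycle_q(qx_at_age(stream, ages), cd))
}

make_trace <- function(core, cycles, ages, frac_on, cycle_days, strategy) {
  tr <- data.frame(cycle = cycles, age = ages,
                   alive = core$alive, dead = core$dead,
                   inc_ocs = core$inc_ocs, inc_ed = core$inc_ed,
                   inc_hosp = core$inc_hosp,
                   frac_on_treatment = frac_on)
  attr(tr, "cycle_days") <- cycle_days
  attr(tr, "strategy") <- strategy
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

truncate_trace <- function(tr, tol = 1e-9) {
  idx <- which(tr$alive < tol)
  if (length(idx) > 0L && idx[1] < nrow(tr)) {
    tr <- tr[seq_len(idx[1]), , drop = FALSE]
    rownames(tr) <- NULL
  }
  tr
}

#' Mix adherent and reverted sub-cohort traces
#'
#' From the waning cycle onward a fraction of the add-on cohort reverts to
#' comparator inputs (losing both the treatment effect and the drug cost);
#' the blended trace is the occupancy-weighted mixture of the fully adherent
#' sub-cohort and the reverting sub-cohort. `frac_on_treatment` in the blend
#' is the on-treatment share of the *alive* mass.
#'
#' @param adherent,reverted `cohort_trace` objects for the two sub-cohorts
#'   (same cycle grid).
#' @param adherence The `adherence` component of a `parameter_set` (fields
#'   `discontinuation`, `waning_cycle`).
#' @return A blended `cohort_trace`.
#' @export
blend_adherence <- function(adherent, reverted, adherence) {
  d <- adherence$discontinuation$base
  if (d < 0 || d > 1) stop("discontinuation fraction must lie in [0, 1]",
                           call. = FALSE)
  n <- min(nrow(adherent), nrow(reverted))
  a <- adherent[seq_len(n), ]; r <- reverted[seq_len(n), ]
  # written as r + (1-d)(a - r) so identical sub-traces blend to themselves
  # exactly and the degenerate weights reproduce a sub-trace exactly
  mix <- function(col) {
    if (d == 0) return(a[[col]])
    if (d == 1) return(r[[col]])
    r[[col]] + (1 - d) * (a[[col]] - r[[col]])
  }
  alive <- mix("alive")
  on_mass <- (1 - d) * a$alive * a$frac_on_treatment +
    d * r$alive * r$frac_on_treatment
  out <- data.frame(cycle = a$cycle, age = a$age,
                    alive = alive, dead = mix("dead"),
                    inc_ocs = mix("inc_ocs"), inc_ed = mix("inc_ed"),
                    inc_hosp = mix("inc_hosp"),
                    frac_on_treatment = ifelse(alive > 0, on_mass / alive, 0))
  attr(out, "cycle_days") <- attr(adherent, "cycle_days")
  attr(out, "strategy") <- "add_on"
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Propagate the cohort over the horizon
#'
#' Runs the Markov cohort for one strategy: per-cycle background mortality
#' from the life table (age advancing by the cycle length), exacerbation
#' event incidence by channel, asthma case fatality on the hospitalization
#' channel, and — for the add-on strategy — adherence waning (a fraction of
#' the cohort reverts to comparator inputs from the waning cycle onward).
#' A lifetime horizon runs to the terminal life-table age or until the alive
#' mass falls below 1e-9, whichever comes first.
#'
#' @param params A `parameter_set`.
#' @param strategy `"comparator"` (ICS+LABA) or `"add_on"` (tiotropium add-on).
#' @param scenario A `scenario_spec`.
#' @param life_table A `life_table`.
#' @return A `cohort_trace` data frame: one row per cycle boundary with
#'   columns `cycle`, `age`, `alive`, `dead`, `inc_ocs`, `inc_ed`,
#'   `inc_hosp`, `frac_on_treatment`.
#' @examples
#' lt <- synthetic_life_table()
#' tr <- run_cohort(table1_fixture(), "comparator", scenario_spec(), lt)
#' head(tr)
#' @export
run_cohort <- function(params, strategy = c("comparator", "add_on"),
                       scenario = scenario_spec(),
                       life_table = synthetic_life_table()) {
  strategy <- match.arg(strategy)
  stream <- qx_stream(life_table, scenario$prop_female)
  if (floor(scenario$start_age) < stream$min_age ||
      scenario$start_age > stream$max_age) {
    stop("scenario start age outside the life-table range", call. = FALSE)
  }
  plan <- plan_cycles(params, scenario, stream)
  cd <- params$econ$cycle_days
  cfr <- params$events$asthma_case_fatality_hosp
  cycles <- 0:plan$K
  p_u <- event_channel_probs(params, on_treatment = FALSE)
  if (strategy == "comparator") {
    core <- cohort_core(plan$p_bg, p_u["ocs"], p_u["ed"], p_u["hosp"], cfr)
    return(truncate_trace(make_trace(core, cycles, plan$ages, 0, cd,
                                     strategy)))
  }
  p_t <- event_channel_probs(params, on_treatment = TRUE)
  w <- params$adherence$waning_cycle
  post <- cycles >= w  # regime switch for the reverting sub-cohort
  full <- function(x) rep(x, plan$K + 1L)
  adherent <- make_trace(
    cohort_core(plan$p_bg, full(p_t["ocs"]), full(p_t["ed"]),
                full(p_t["hosp"]), cfr),
    cycles, plan$ages, 1, cd, "add_on")
  reverted <- make_trace(
    cohort_core(plan$p_bg,
                ifelse(post, p_u["ocs"], p_t["ocs"]),
                ifelse(post, p_u["ed"], p_t["ed"]),
                ifelse(post, p_u["hosp"], p_t["hosp"]), cfr),
    cycles, plan$ages, as.numeric(!post), cd, "add_on")
  truncate_trace(blend_adherence(adherent, reverted, params$adherence))
}

#' Write a cohort trace as CSV
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
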