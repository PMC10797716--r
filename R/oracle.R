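#' Individual-level microsimulation oracle
#'
#' Simulates individuals event-by-event with exactly the per-cycle
#' probabilities the cohort engine uses (background death first, then at
#' most one exacerbation among survivors, case fatality on the
#' hospitalization channel; for the add-on strategy each individual is a
#' discontinuer with the discontinuation probability and reverts to
#' comparator inputs at the waning cycle). Returns the empirical trace on
#' the same grid as [run_cohort()]. This is a verification oracle, not a
#' production engine: the cohort recursion should agree with it to within
#' Monte Carlo error.
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed (`NULL` leaves the RNG state untouched).
#' @return A `cohort_trace` data frame of empirical proportions.
#' @export
oracle_simulate <- function(params, strategy = c("comparator", "add_on"),
                            scenario = scenario_spec(),
                            life_table = synthetic_life_table(),
                            n_individuals = 10000L, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_individuals >= 1L)
  if (!is.null(seed)) set.seed(seed)
  stream <- qx_stream(life_table, scenario$prop_female)
  plan <- plan_cycles(params, scenario, stream)
  cd <- params$econ$cycle_days
  cfr <- params$events$asthma_case_fatality_hosp
  p_u <- event_channel_probs(params, on_treatment = FALSE)
  p_t <- event_channel_probs(params, on_treatment = TRUE)
  w <- params$adherence$waning_cycle
  n <- n_individuals
  alive <- rep(TRUE, n)
  disc <- if (strategy == "add_on") {
    stats::runif(n) < params$adherence$discontinuation$base
  } else {
    rep(FALSE, n)
  }
  K <- plan$K
  m <- matrix(0, nrow = K + 1L, ncol = 6L)
  colnames(m) <- c("alive", "inc_ocs", "inc_ed", "inc_hosp", "on_trt", "dead")
  for (k in 0:K) {
    on_trt <- if (strategy == "add_on") (!disc | k < w) else rep(FALSE, n)
    m[k + 1L, "alive"] <- sum(alive)
    m[k + 1L, "on_trt"] <- sum(alive & on_trt)
    die_bg <- alive & (stats::runif(n) < plan$p_bg[k + 1L])
    surv <- alive & !die_bg
    # one categorical event draw per survivor: [0,hosp) hosp,
    # [hosp,hosp+ed) ED, [hosp+ed, hosp+ed+ocs) OCS, else none
    u <- stats::runif(n)
    p1 <- ifelse(on_trt, p_t["hosp"], p_u["hosp"])
    p2 <- p1 + ifelse(on_trt, p_t["ed"], p_u["ed"])
    p3 <- p2 + ifelse(on_trt, p_t["ocs"], p_u["ocs"])
    hosp <- surv & u < p1
    ed <- surv & u >= p1 & u < p2
    ocs <- surv & u >= p2 & u < p3
    m[k + 1L, "inc_ocs"] <- sum(ocs)
    m[k + 1L, "inc_ed"] <- sum(ed)
    m[k + 1L, "inc_hosp"] <- sum(hosp)
    die_asthma <- hosp & (stats::runif(n) < cfr)
    alive <- surv & !die_asthma
  }
  prop <- m / n
  tr <- data.frame(cycle = 0:K, age = plan$ages,
                   alive = prop[, "alive"], dead = 1 - prop[, "alive"],
                   inc_ocs = prop[, "inc_ocs"], inc_ed = prop[, "inc_ed"],
                   inc_hosp = prop[, "inc_hosp"],
                   frac_on_treatment = ifelse(prop[, "alive"] > 0,
                                              prop[, "on_trt"] /
                                                prop[, "alive"], 0))
  attr(tr, "cycle_days") <- cd
  attr(tr, "strategy") <- strategy
  attr(tr, "n_individuals") <- n
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}
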