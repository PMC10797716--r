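#' Point estimate with a sensitivity range
#'
#' A `point_range` bundles a base-case value with the lower/upper bounds used
#' in sensitivity analyses. Ranges are interpreted as 95% intervals when a
#' sampling distribution is fitted from them (see [beta_from_mean_range()]).
#'
#' @param base Base-case value.
#' @param lower,upper Range bounds; default to `base` (degenerate range).
#' @return An object of class `point_range` with fields `base`, `lower`,
#'   `upper`.
#' @examples
#' point_range(0.72, 0.62, 0.83)
#' @export
point_range <- function(base, lower = base, upper = base) {
  stopifnot(is.numeric(base), length(base) == 1L,
            is.numeric(lower), length(lower) == 1L,
            is.numeric(upper), length(upper) == 1L)
  if (lower > base || base > upper) {
    stop("point_range requires lower <= base <= upper (got ",
         lower, " / ", base, " / ", upper, ")", call. = FALSE)
  }
  structure(list(base = as.numeric(base), lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "point_range")
}

#' @export
print.point_range <- function(x, ...) {
  cat(sprintf("%g [%g, %g]\n", x$base, x$lower, x$upper))
  invisible(x)
}

is_point_range <- function(x) inherits(x, "point_range")

#' Fit a beta distribution from a mean and a 95% range
#'
#' Method-of-moments fit: the mean is matched exactly and the standard
#' deviation is taken as `(upper - lower) / 3.92`, i.e. the range is read as
#' a 95% interval. Used for utilities, utility decrements, the relative risk
#' (which lies in (0,1) here) and per-cycle transition probabilities.
#'
#' @param mean Target mean, in (0, 1).
#' @param lower,upper Range bounds with `0 < lower <= mean <= upper < 1`.
#' @return A `dist_spec` list: `family` (`"beta"` or `"fixed"` when the range
#'   is degenerate), `shape1`, `shape2`, and the implied `mean` and `sd`.
#' @examples
#' beta_from_mean_range(0.74, 0.56, 0.93)
#' @seealso [gamma_from_mean_range()]
#' @export
beta_from_mean_range <- function(mean, lower, upper) {
  stopifnot(is.numeric(mean), is.numeric(lower), is.numeric(upper))
  if (lower > mean || mean > upper) {
    stop("beta fit requires lower <= mean <= upper", call. = FALSE)
  }
  if (upper == lower) {
    return(fixed_dist(mean))
  }
  if (mean <= 0 || mean >= 1 || lower <= 0 || upper >= 1) {
    stop("beta fit requires 0 < lower <= mean <= upper < 1", call. = FALSE)
  }
  sd <- (upper - lower) / 3.92
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("beta fit infeasible: implied variance ", signif(v, 4),
         " >= mean*(1-mean) = ", signif(mean * (1 - mean), 4), call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  structure(list(family = "beta",
                 shape1 = mean * nu, shape2 = (1 - mean) * nu,
                 mean = mean, sd = sd),
            class = "dist_spec")
}

#' Fit a gamma distribution from a mean and a 95% range
#'
#' Method-of-moments fit for cost parameters: mean matched exactly,
#' sd = `(upper - lower) / 3.92`. A degenerate range yields a fixed-value
#' spec.
#'
#' @param mean Target mean, positive.
#' @param lower,upper Range bounds with `0 < lower <= mean <= upper`.
#' @return A `dist_spec` list with `family` `"gamma"` (fields `shape`,
#'   `scale`) or `"fixed"`.
#' @examples
#' gamma_from_mean_range(2648, 1986, 3310)
#' @export
gamma_from_mean_range <- function(mean, lower, upper) {
  stopifnot(is.numeric(mean), is.numeric(lower), is.numeric(upper))
  if (mean <= 0) stop("gamma fit requires a positive mean", call. = FALSE)
  if (lower > mean || mean > upper) {
    stop("gamma fit requires lower <= mean <= upper", call. = FALSE)
  }
  if (upper == lower) {
    return(fixed_dist(mean))
  }
  sd <- (upper - lower) / 3.92
  structure(list(family = "gamma",
                 shape = (mean / sd)^2, scale = sd^2 / mean,
                 mean = mean, sd = sd),
            class = "dist_spec")
}

fixed_dist <- function(value) {
  structure(list(family = "fixed", value = value, mean = value, sd = 0),
            class = "dist_spec")
}

#' Log-normal fallback fit (mean/sd on the natural scale)
#'
#' Used only when a relative risk with range touching or exceeding 1 is
#' supplied, where the default beta distribution has no support.
#' @noRd
lnorm_from_mean_range <- function(mean, lower, upper) {
  sd <- (upper - lower) / 3.92
  if (sd == 0) return(fixed_dist(mean))
  s2 <- log(1 + (sd / mean)^2)
  structure(list(family = "lnorm",
                 meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2),
                 mean = mean, sd = sqrt(s2) * 0 + sd),
            class = "dist_spec")
}

#' Analytic mean and sd of a fitted distribution
#' @param spec A `dist_spec`.
#' @return A numeric value.
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
         fixed = spec$value,
         beta  = spec$shape1 / (spec$shape1 + spec$shape2),
         gamma = spec$shape * spec$scale,
         lnorm = exp(spec$meanlog + spec$sdlog^2 / 2),
         stop("unknown family"))
}

#' @rdname dist_mean
#' @export
dist_sd <- function(spec) {
  switch(spec$family,
         fixed = 0,
         beta  = {
           a <- spec$shape1; b <- spec$shape2
           sqrt(a * b / ((a + b)^2 * (a + b + 1)))
         },
         gamma = sqrt(spec$shape) * spec$scale,
         lnorm = sqrt((exp(spec$sdlog^2) - 1)) *
           exp(spec$meanlog + spec$sdlog^2 / 2),
         stop("unknown family"))
}

#' Draw from a fitted distribution
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n = 1L) {
  switch(spec$family,
         fixed = rep(spec$value, n),
         beta  = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         lnorm = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         stop("unknown family"))
}

as_point_range <- function(x, field) {
  if (is_point_range(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(point_range(x))
  if (is.list(x) && !is.null(x$base)) {
    return(point_range(x$base,
                       if (is.null(x$lower)) x$base else x$lower,
                       if (is.null(x$upper)) x$base else x$upper))
  }
  stop("field '", field, "' is not a valid point/range specification",
       call. = FALSE)
}

#' Assemble a full model parameter set
#'
#' Builds the `parameter_set` container holding every model input: costs
#' (2023 US$), utilities and utility decrements, the treatment effect
#' (relative risk on the exacerbation rate), event rates and their channel
#' split, adherence, and economic settings. Usually obtained from
#' [load_parameter_set()] or [table1_fixture()] rather than called directly.
#'
#' @param costs,utilities,effect,events,adherence,econ Named lists mirroring
#'   the packaged YAML fixture (see
#'   `system.file("extdata", "table1_parameters.yaml", package = "tiocue")`).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(costs, utilities, effect, events, adherence, econ) {
  pr <- function(section, nm, field) {
    as_point_range(section[[nm]], field)
  }
  ps <- structure(list(
    costs = list(
      drug_per_4wk            = pr(costs, "drug_per_4wk", "costs.drug_per_4wk"),
      controlled_state_annual = pr(costs, "controlled_state_annual",
                                   "costs.controlled_state_annual"),
      ocs_burst_per_episode   = pr(costs, "ocs_burst_per_episode",
                                   "costs.ocs_burst_per_episode"),
      ed_visit_per_episode    = pr(costs, "ed_visit_per_episode",
                                   "costs.ed_visit_per_episode"),
      hospitalization_per_episode = pr(costs, "hospitalization_per_episode",
                                       "costs.hospitalization_per_episode")),
    utilities = list(
      controlled     = pr(utilities, "controlled", "utilities.controlled"),
      decrement_ocs  = pr(utilities, "decrement_ocs", "utilities.decrement_ocs"),
      decrement_ed   = pr(utilities, "decrement_ed", "utilities.decrement_ed"),
      decrement_hosp = pr(utilities, "decrement_hosp",
                          "utilities.decrement_hosp")),
    effect = list(
      rr_exacerbation = pr(effect, "rr_exacerbation", "effect.rr_exacerbation")),
    events = list(
      exacerbation_annual_rate = pr(events, "exacerbation_annual_rate",
                                    "events.exacerbation_annual_rate"),
      split_ocs  = events$split_ocs,
      split_ed   = events$split_ed,
      split_hosp = events$split_hosp,
      asthma_case_fatality_hosp = events$asthma_case_fatality_hosp),
    adherence = list(
      discontinuation = pr(adherence, "discontinuation",
                           "adherence.discontinuation"),
      waning_cycle = as.integer(adherence$waning_cycle)),
    econ = list(
      annual_discount_rate = pr(econ, "annual_discount_rate",
                                "econ.annual_discount_rate"),
      wtp_per_qaly = as.numeric(econ$wtp_per_qaly),
      cycle_days   = as.numeric(econ$cycle_days),
      cop_per_usd  = as.numeric(econ$cop_per_usd))),
    class = "parameter_set")
  ps
}

#' Validate a parameter set
#'
#' Checks every container invariant and returns the violations as data, not
#' exceptions: an empty data frame means the set is valid.
#'
#' @param params A `parameter_set`.
#' @return A data frame with columns `field`, `rule`, `value`; zero rows when
#'   all invariants hold.
#' @examples
#' nrow(validate_parameter_set(table1_fixture())) # 0
#' @export
validate_parameter_set <- function(params) {
  bad <- list()
  note <- function(field, rule, value) {
    bad[[length(bad) + 1L]] <<- data.frame(
      field = field, rule = rule, value = as.numeric(value)[1],
      stringsAsFactors = FALSE)
  }
  chk_range <- function(x, field) {
    if (!is_point_range(x)) { note(field, "must be a point_range", NA); return() }
    if (x$lower > x$base || x$base > x$upper)
      note(field, "lower <= base <= upper", x$base)
  }
  for (nm in names(params$costs)) {
    x <- params$costs[[nm]]
    chk_range(x, paste0("costs.", nm))
    if (is_point_range(x) && x$lower < 0)
      note(paste0("costs.", nm), "costs must be >= 0", x$lower)
  }
  u <- params$utilities
  chk_range(u$controlled, "utilities.controlled")
  if (u$controlled$base < 0 || u$controlled$base > 1)
    note("utilities.controlled", "utility must lie in [0, 1]", u$controlled$base)
  for (nm in c("decrement_ocs", "decrement_ed", "decrement_hosp")) {
    chk_range(u[[nm]], paste0("utilities.", nm))
    if (u[[nm]]$lower < 0)
      note(paste0("utilities.", nm), "decrement must be >= 0", u[[nm]]$lower)
  }
  max_dec <- max(u$decrement_ocs$base, u$decrement_ed$base,
                 u$decrement_hosp$base)
  if (u$controlled$base - max_dec < -1)
    note("utilities", "controlled - max decrement must be >= -1",
         u$controlled$base - max_dec)
  rr <- params$effect$rr_exacerbation
  chk_range(rr, "effect.rr_exacerbation")
  if (rr$lower <= 0)
    note("effect.rr_exacerbation", "relative risk must be > 0", rr$lower)
  ev <- params$events
  chk_range(ev$exacerbation_annual_rate, "events.exacerbation_annual_rate")
  if (ev$exacerbation_annual_rate$lower < 0)
    note("events.exacerbation_annual_rate", "rate must be >= 0",
         ev$exacerbation_annual_rate$lower)
  splits <- c(ev$split_ocs, ev$split_ed, ev$split_hosp)
  if (any(splits < 0 | splits > 1))
    note("events.split", "split proportions must lie in [0, 1]", min(splits))
  if (abs(sum(splits) - 1) > 1e-12)
    note("events.split", "split proportions must sum to 1", sum(splits))
  if (ev$asthma_case_fatality_hosp < 0 || ev$asthma_case_fatality_hosp > 1)
    note("events.asthma_case_fatality_hosp", "case fatality must lie in [0, 1]",
         ev$asthma_case_fatality_hosp)
  ad <- params$adherence
  chk_range(ad$discontinuation, "adherence.discontinuation")
  if (ad$discontinuation$lower < 0 || ad$discontinuation$upper > 1)
    note("adherence.discontinuation", "fraction must lie in [0, 1]",
         ad$discontinuation$base)
  if (is.na(ad$waning_cycle) || ad$waning_cycle < 1)
    note("adherence.waning_cycle", "waning cycle must be >= 1", ad$waning_cycle)
  ec <- params$econ
  chk_range(ec$annual_discount_rate, "econ.annual_discount_rate")
  if (ec$annual_discount_rate$lower < 0 || ec$annual_discount_rate$upper > 1)
    note("econ.annual_discount_rate", "discount rate must lie in [0, 1]",
         ec$annual_discount_rate$base)
  if (ec$wtp_per_qaly <= 0)
    note("econ.wtp_per_qaly", "willingness-to-pay must be > 0", ec$wtp_per_qaly)
  if (ec$cycle_days <= 0)
    note("econ.cycle_days", "cycle length must be > 0", ec$cycle_days)
  if (length(bad) == 0L) {
    return(data.frame(field = character(), rule = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

deep_merge <- function(base, override) {
  if (!is.list(override)) return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      deep_merge(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Load (and optionally override) the model parameter set
#'
#' Reads the packaged base-case fixture and merges user overrides on top,
#' then validates. Overrides may be a YAML file path or a nested list using
#' the same section/field names as the fixture; a `{base, lower, upper}`
#' mapping or a bare number (degenerate range) are both accepted for
#' uncertain quantities.
#'
#' @param config `NULL` (packaged defaults), a YAML file path, or a nested
#'   list of overrides.
#' @return A validated `parameter_set`.
#' @examples
#' p <- load_parameter_set(list(econ = list(annual_discount_rate =
#'   list(base = 0, lower = 0, upper = 0))))
#' p$econ$annual_discount_rate$base
#' @export
load_parameter_set <- function(config = NULL) {
  path <- system.file("extdata", "table1_parameters.yaml", package = "tiocue")
  defaults <- yaml::read_yaml(path)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) {
    if (!is.list(config)) stop("config must be a file path or a list",
                               call. = FALSE)
    defaults <- deep_merge(defaults, config)
  }
  ps <- parameter_set(defaults$costs, defaults$utilities, defaults$effect,
                      defaults$events, defaults$adherence, defaults$econ)
  viol <- validate_parameter_set(ps)
  if (nrow(viol) > 0L) {
    stop("invalid parameter set:\n",
         paste(sprintf("  %s: %s (value %g)", viol$field, viol$rule,
                       viol$value), collapse = "\n"),
         call. = FALSE)
  }
  ps
}

#' Build the sampling distributions behind a parameter set
#'
#' Beta for the relative risk, utility, utility decrements, the per-cycle
#' exacerbation probability (the annual rate converted to the cycle grid) and
#' the discontinuation fraction; gamma for the five costs. Economic settings
#' are held fixed in probabilistic analysis. Construction fails immediately
#' if any fit is infeasible, so sampling never fails at draw time. A relative
#' risk with range reaching 1 or above falls back to a log-normal fit with a
#' warning.
#'
#' @param params A `parameter_set`.
#' @return Named list of `dist_spec` objects.
#' @export
parameter_distributions <- function(params) {
  pr <- function(x) c(x$base, x$lower, x$upper)
  beta_pr <- function(x) beta_from_mean_range(x$base, x$lower, x$upper)
  gamma_pr <- function(x) gamma_from_mean_range(x$base, x$lower, x$upper)
  rr <- params$effect$rr_exacerbation
  rr_spec <- if (rr$upper < 1) {
    beta_pr(rr)
  } else {
    warning("relative-risk range reaches 1; falling back to a log-normal fit",
            call. = FALSE)
    lnorm_from_mean_range(rr$base, rr$lower, rr$upper)
  }
  # the annual exacerbation rate (> 1) is sampled as its per-cycle transition
  # probability, which has beta support
  cd <- params$econ$cycle_days
  er <- params$events$exacerbation_annual_rate
  p3 <- rate_to_cycle_probability(pr(er), cd)
  list(
    rr_exacerbation   = rr_spec,
    utility_controlled = beta_pr(params$utilities$controlled),
    decrement_ocs     = beta_pr(params$utilities$decrement_ocs),
    decrement_ed      = beta_pr(params$utilities$decrement_ed),
    decrement_hosp    = beta_pr(params$utilities$decrement_hosp),
    p_exacerbation_cycle = beta_from_mean_range(p3[1], p3[2], p3[3]),
    discontinuation   = beta_pr(params$adherence$discontinuation),
    cost_drug         = gamma_pr(params$costs$drug_per_4wk),
    cost_controlled   = gamma_pr(params$costs$controlled_state_annual),
    cost_ocs          = gamma_pr(params$costs$ocs_burst_per_episode),
    cost_ed           = gamma_pr(params$costs$ed_visit_per_episode),
    cost_hosp         = gamma_pr(params$costs$hospitalization_per_episode))
}

#' Vectorized parameter draws for probabilistic analysis
#'
#' Draws `n` joint parameter samples (independent across parameters) in a
#' fixed column order, so a draw stream is fully reproducible from the RNG
#' state. Used by [run_psa()] and [sample_parameter_set()].
#'
#' @param params A `parameter_set`.
#' @param n Number of joint draws.
#' @return Data frame with one column per sampled parameter; the per-cycle
#'   exacerbation probability draw is returned converted back to an annual
#'   rate (`exacerbation_annual_rate`).
#' @export
draw_parameters <- function(params, n) {
  d <- parameter_distributions(params)
  cd <- params$econ$cycle_days
  order_ <- c("rr_exacerbation", "utility_controlled", "decrement_ocs",
              "decrement_ed", "decrement_hosp", "p_exacerbation_cycle",
              "discontinuation", "cost_drug", "cost_controlled", "cost_ocs",
              "cost_ed", "cost_hosp")
  # one joint draw per row (all parameters of draw i before draw i+1), so
  # draw i is reproducible from the seed regardless of the total draw count
  m <- matrix(NA_real_, nrow = n, ncol = length(order_),
              dimnames = list(NULL, order_))
  for (i in seq_len(n)) {
    for (j in order_) m[i, j] <- dist_sample(d[[j]], 1L)
  }
  out <- as.data.frame(m)
  out$exacerbation_annual_rate <-
    cycle_probability_to_rate(out$p_exacerbation_cycle, cd)
  out$p_exacerbation_cycle <- NULL
  out
}

set_base <- function(pr, value) point_range(value, min(pr$lower, value),
                                            max(pr$upper, value))

apply_draw <- function(params, draw) {
  p <- params
  p$effect$rr_exacerbation <- set_base(p$effect$rr_exacerbation,
                                       draw$rr_exacerbation)
  p$utilities$controlled <- set_base(p$utilities$controlled,
                                     draw$utility_controlled)
  p$utilities$decrement_ocs <- set_base(p$utilities$decrement_ocs,
                                        draw$decrement_ocs)
  p$utilities$decrement_ed <- set_base(p$utilities$decrement_ed,
                                       draw$decrement_ed)
  p$utilities$decrement_hosp <- set_base(p$utilities$decrement_hosp,
                                         draw$decrement_hosp)
  p$events$exacerbation_annual_rate <-
    set_base(p$events$exacerbation_annual_rate, draw$exacerbation_annual_rate)
  p$adherence$discontinuation <- set_base(p$adherence$discontinuation,
                                          draw$discontinuation)
  p$costs$drug_per_4wk <- set_base(p$costs$drug_per_4wk, draw$cost_drug)
  p$costs$controlled_state_annual <- set_base(p$costs$controlled_state_annual,
                                              draw$cost_controlled)
  p$costs$ocs_burst_per_episode <- set_base(p$costs$ocs_burst_per_episode,
                                            draw$cost_ocs)
  p$costs$ed_visit_per_episode <- set_base(p$costs$ed_visit_per_episode,
                                           draw$cost_ed)
  p$costs$hospitalization_per_episode <-
    set_base(p$costs$hospitalization_per_episode, draw$cost_hosp)
  p
}

#' Draw one probabilistic realization of a parameter set
#'
#' Replaces every sampled parameter's base value with a random draw from its
#' fitted distribution (ranges untouched); economic settings, the event
#' split and the case fatality stay fixed. Deterministic under a fixed RNG
#' state (`set.seed`). Degenerate ranges reproduce the base case exactly.
#'
#' @param params A `parameter_set`.
#' @return A `parameter_set` with sampled base values.
#' @examples
#' set.seed(1); s <- sample_parameter_set(table1_fixture())
#' s$effect$rr_exacerbation$base
#' @export
sample_parameter_set <- function(params) {
  apply_draw(params, draw_parameters(params, 1L))
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  RR exacerbation: %g [%g, %g]\n",
              x$effect$rr_exacerbation$base, x$effect$rr_exacerbation$lower,
              x$effect$rr_exacerbation$upper))
  cat(sprintf("  exacerbation rate: %g /yr; split OCS/ED/hosp %g/%g/%g\n",
              x$events$exacerbation_annual_rate$base, x$events$split_ocs,
              x$events$split_ed, x$events$split_hosp))
  cat(sprintf("  drug cost: %g per 4 weeks; WTP %g US$/QALY; cycle %g d\n",
              x$costs$drug_per_4wk$base, x$econ$wtp_per_qaly,
              x$econ$cycle_days))
  invisible(x)
}
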