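# Shared fixtures: short-horizon scenarios and perturbed parameter sets,
# built in code so every test input is reproducible.

base_params <- table1_fixture()
default_lt <- synthetic_life_table()

# a high-mortality table over a short age span keeps property tests fast
quick_lt <- function() synthetic_life_table(a = 0.02, b = 5e-4, c = 0.1,
                                            ages = 18:80)

short_scenario <- function(horizon = 60, start_age = 40) {
  scenario_spec(start_age = start_age, horizon = horizon)
}

# collapse every sensitivity range onto the base value
degenerate_params <- function(p = base_params) {
  squash <- function(x) if (inherits(x, "point_range")) point_range(x$base)
  else x
  for (sec in c("costs", "utilities", "effect", "events", "adherence",
                "econ")) {
    p[[sec]] <- lapply(p[[sec]], squash)
  }
  class(p) <- "parameter_set"
  p
}

set_param <- function(p, section, field, base, lower = base, upper = base) {
  p[[section]][[field]] <- point_range(base, lower, upper)
  p
}

# null-effect configuration: RR = 1 and zero drug cost
null_effect_params <- function(p = base_params) {
  p <- set_param(p, "effect", "rr_exacerbation", 1)
  set_param(p, "costs", "drug_per_4wk", 0)
}

# hand-built PSA draw container for decision-statistic tests
make_psa_draws <- function(delta_cost, delta_qaly, wtp = 5180,
                           cost_comparator = 100, qaly_comparator = 1) {
  n <- length(delta_cost)
  d <- data.frame(draw = seq_len(n),
                  cost_comparator = rep(cost_comparator, n),
                  qaly_comparator = rep(qaly_comparator, n),
                  cost_addon = cost_comparator + delta_cost,
                  qaly_addon = qaly_comparator + delta_qaly)
  d$delta_cost <- d$cost_addon - d$cost_comparator
  d$delta_qaly <- d$qaly_addon - d$qaly_comparator
  attr(d, "wtp") <- wtp
  attr(d, "n_runs") <- n
  class(d) <- c("psa_draws", "data.frame")
  d
}

# constant-reward synthetic trace (no events, whole cohort alive)
constant_trace <- function(n_cycles, cycle_days = 14) {
  tr <- data.frame(cycle = 0:n_cycles, age = 40 + (0:n_cycles) *
                     cycle_days / 365.25,
                   alive = 1, dead = 0, inc_ocs = 0, inc_ed = 0,
                   inc_hosp = 0, frac_on_treatment = 0)
  attr(tr, "cycle_days") <- cycle_days
  attr(tr, "strategy") <- "comparator"
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

expect_trace_valid <- function(tr, tol = 1e-12) {
  expect_true(all(abs(tr$alive + tr$dead - 1) <= tol))
  expect_true(all(tr$alive >= -tol & tr$alive <= 1 + tol))
  expect_true(all(diff(tr$dead) >= -tol))
  expect_true(all(diff(tr$alive) <= tol))
  for (col in c("inc_ocs", "inc_ed", "inc_hosp")) {
    expect_true(all(tr[[col]] >= -tol & tr[[col]] <= 1 + tol))
  }
}
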