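# Rate/probability conversions, transition construction, cohort propagation,
# adherence blending, and engine/microsimulation equivalence.

test_that("rate-to-probability conversion matches its closed form", {
  expect_identical(rate_to_cycle_probability(0, 14), 0)
  expect_equal(rate_to_cycle_probability(1.14, 14), 0.04275518,
               tolerance = 1e-7)
  expect_equal(rate_to_cycle_probability(1e6, 14), 1, tolerance = 1e-12)
  r <- c(0.1, 0.5, 1.14, 3)
  expect_true(all(diff(rate_to_cycle_probability(r, 14)) > 0))
  expect_error(rate_to_cycle_probability(-1, 14), ">= 0")
  # inverse conversion round trips
  expect_equal(cycle_probability_to_rate(
    rate_to_cycle_probability(r, 14), 14), r, tolerance = 1e-12)
})

test_that("the relative risk acts multiplicatively on the rate scale", {
  expect_equal(apply_relative_risk(1.14, 0.72), 0.8208, tolerance = 1e-12)
  expect_identical(apply_relative_risk(2.5, 1), 2.5)
  expect_identical(apply_relative_risk(0, 0.3), 0)
  expect_error(apply_relative_risk(1, 0), "> 0")
})

test_that("cycle transitions carry the treatment effect and the life table", {
  tr_on <- build_cycle_transition(base_params, TRUE, 40, default_lt)
  tr_off <- build_cycle_transition(base_params, FALSE, 40, default_lt)
  # frozen closed-form value: split 0.25, rate 1.14, RR 0.72, 14-day cycle
  expect_equal(tr_on$p_event_hosp, 0.00783445, tolerance = 1e-6)
  expect_equal(tr_on$p_event_hosp,
               1 - exp(-0.25 * 1.14 * 0.72 * 14 / 365.25), tolerance = 1e-12)
  expect_lt(tr_on$p_event_ocs, tr_off$p_event_ocs)
  expect_equal(tr_on$p_death_background,
               annual_q_to_cycle_q(default_lt$qx[default_lt$age == 40], 14),
               tolerance = 1e-12)

  # RR = 1: on- and off-treatment transitions coincide
  p1 <- set_param(base_params, "effect", "rr_exacerbation", 1)
  expect_identical(build_cycle_transition(p1, TRUE, 40, default_lt),
                   build_cycle_transition(p1, FALSE, 40, default_lt))

  # degenerate split: only the OCS channel is active
  ps <- base_params
  ps$events$split_ocs <- 1; ps$events$split_ed <- 0; ps$events$split_hosp <- 0
  t1 <- build_cycle_transition(ps, FALSE, 40, default_lt)
  expect_identical(t1$p_event_ed, 0)
  expect_identical(t1$p_event_hosp, 0)
  expect_gt(t1$p_event_ocs, 0)
})

test_that("occupancy is conserved and death is absorbing on randomized scenarios", {
  set.seed(101)
  for (i in 1:5) {
    p <- sample_parameter_set(base_params)
    h <- list(40, 120, "lifetime")[[sample(3, 1)]]
    sc <- scenario_spec(start_age = sample(20:70, 1), horizon = h)
    for (strat in c("comparator", "add_on")) {
      expect_trace_valid(run_cohort(p, strat, sc, default_lt))
    }
  }
})

test_that("boundary mortality behaves: no deaths and certain death", {
  # no background mortality, no case fatality: everyone stays alive
  lt0 <- synthetic_life_table(a = 0, b = 1e-300, c = 0.01, ages = 18:60)
  p0 <- base_params
  p0$events$asthma_case_fatality_hosp <- 0
  tr <- run_cohort(p0, "comparator", short_scenario(20, 30), lt0)
  expect_equal(tr$alive, rep(1, 21), tolerance = 0)

  # qx = 1 at the start age: the cohort is fully dead after one cycle
  lt1 <- synthetic_life_table(ages = 18:60)
  lt1$qx[] <- 1
  tr1 <- run_cohort(base_params, "comparator", short_scenario(5, 30), lt1)
  expect_identical(tr1$alive[1], 1)
  expect_identical(tr1$alive[2], 0)
})

test_that("the add-on arm has lower exacerbation incidence while treated", {
  sc <- scenario_spec()
  comp <- run_cohort(base_params, "comparator", sc, default_lt)
  addon <- run_cohort(base_params, "add_on", sc, default_lt)
  n <- min(nrow(comp), nrow(addon))
  inc <- function(tr) tr$inc_ocs + tr$inc_ed + tr$inc_hosp
  cum_c <- cumsum(inc(comp)[1:n]); cum_a <- cumsum(inc(addon)[1:n])
  expect_true(all(cum_a <= cum_c + 1e-12))
  w <- base_params$adherence$waning_cycle
  expect_true(all(inc(addon)[2:w] < inc(comp)[2:w]))
})

test_that("blending is the occupancy-weighted mixture of the sub-cohorts", {
  sc <- short_scenario(120, 45)
  d0 <- base_params
  d0$adherence$discontinuation <- point_range(0)
  d1 <- base_params
  d1$adherence$discontinuation <- point_range(1)
  adherent <- run_cohort(d0, "add_on", sc, default_lt)
  reverted <- run_cohort(d1, "add_on", sc, default_lt)
  blended <- run_cohort(base_params, "add_on", sc, default_lt)
  for (col in c("alive", "dead", "inc_ocs", "inc_ed", "inc_hosp")) {
    expect_equal(blended[[col]],
                 0.72 * adherent[[col]] + 0.28 * reverted[[col]],
                 tolerance = 1e-12)
  }
  # fully adherent: on treatment forever; fully reverting: off from cycle 8
  expect_true(all(adherent$frac_on_treatment == 1))
  expect_true(all(reverted$frac_on_treatment[reverted$cycle >= 8] == 0))
  expect_true(all(reverted$frac_on_treatment[reverted$cycle < 8] == 1))
})

test_that("a fully reverting cohort follows comparator inputs after waning", {
  sc <- short_scenario(60, 45)
  p <- base_params
  p$adherence$discontinuation <- point_range(1)
  p$events$asthma_case_fatality_hosp <- 0  # keep occupancies identical
  rev <- run_cohort(p, "add_on", sc, default_lt)
  comp <- run_cohort(p, "comparator", sc, default_lt)
  treated <- p
  treated$adherence$discontinuation <- point_range(0)
  adh <- run_cohort(treated, "add_on", sc, default_lt)
  post <- rev$cycle >= p$adherence$waning_cycle
  for (col in c("inc_ocs", "inc_ed", "inc_hosp")) {
    expect_equal(rev[[col]][post], comp[[col]][post], tolerance = 1e-12)
    expect_equal(rev[[col]][!post], adh[[col]][!post], tolerance = 1e-12)
  }
})

test_that("a null effect with free drug makes the strategies identical", {
  p <- null_effect_params()
  sc <- scenario_spec()
  comp <- run_cohort(p, "comparator", sc, default_lt)
  addon <- run_cohort(p, "add_on", sc, default_lt)
  for (col in c("alive", "dead", "inc_ocs", "inc_ed", "inc_hosp")) {
    expect_identical(comp[[col]], addon[[col]])
  }
})

test_that("the cohort engine agrees with the microsimulation oracle", {
  set.seed(202)
  p <- sample_parameter_set(base_params)
  sc <- short_scenario(80, 55)
  for (strat in c("comparator", "add_on")) {
    det <- run_cohort(p, strat, sc, default_lt)
    emp <- oracle_simulate(p, strat, sc, default_lt,
                           n_individuals = 20000, seed = 303)
    n <- min(nrow(det), nrow(emp))
    for (col in c("alive", "inc_ocs", "inc_ed", "inc_hosp")) {
      e <- det[[col]][1:n]
      se <- sqrt(pmax(e * (1 - e), 0) / 20000)
      expect_true(all(abs(emp[[col]][1:n] - e) <= 4 * se + 1e-12),
                  info = paste(strat, col))
    }
  }
})

test_that("deterministic extremes give exact engine/oracle agreement", {
  lt1 <- synthetic_life_table(ages = 18:60)
  lt1$qx[] <- 1
  det <- run_cohort(base_params, "comparator", short_scenario(5, 30), lt1)
  emp <- oracle_simulate(base_params, "comparator", short_scenario(5, 30),
                         lt1, n_individuals = 50, seed = 1)
  expect_identical(emp$alive[1:2], det$alive[1:2])

  # oracle is reproducible under a fixed seed
  a <- oracle_simulate(base_params, "add_on", short_scenario(10, 40),
                       default_lt, n_individuals = 200, seed = 9)
  b <- oracle_simulate(base_params, "add_on", short_scenario(10, 40),
                       default_lt, n_individuals = 200, seed = 9)
  expect_identical(a, b)
})

test_that("trace CSV export round trips", {
  tr <- run_cohort(base_params, "add_on", short_scenario(10, 40), default_lt)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(back$alive, tr$alive, tolerance = 1e-12)
  expect_identical(names(back), names(tr))
})
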