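# Method-of-moments distribution fits, parameter container validation,
# loading/overriding, and probabilistic sampling.

test_that("beta fits reproduce the requested mean and 95%-range sd analytically", {
  cases <- list(c(0.74, 0.56, 0.93),   # controlled-state utility row
                c(0.72, 0.62, 0.83),   # relative-risk row
                c(0.10, 0.08, 0.13),   # OCS decrement row
                c(0.28, 0.24, 0.43))   # discontinuation fraction
  for (cs in cases) {
    spec <- beta_from_mean_range(cs[1], cs[2], cs[3])
    expect_identical(spec$family, "beta")
    expect_equal(dist_mean(spec), cs[1], tolerance = 1e-9)
    expect_equal(dist_sd(spec), (cs[3] - cs[2]) / 3.92, tolerance = 1e-9)
  }
  # frozen shape values for the utility row (range read as a 95% interval)
  spec <- beta_from_mean_range(0.74, 0.56, 0.93)
  v <- ((0.93 - 0.56) / 3.92)^2
  nu <- 0.74 * 0.26 / v - 1
  expect_equal(spec$shape1, 0.74 * nu, tolerance = 1e-12)
  expect_equal(spec$shape2, 0.26 * nu, tolerance = 1e-12)
  expect_equal(spec$shape1, 15.241056, tolerance = 1e-4)
  expect_equal(spec$shape2, 5.354966, tolerance = 1e-4)
})

test_that("a symmetric range yields a symmetric beta", {
  for (d in c(0.05, 0.1, 0.2)) {
    spec <- beta_from_mean_range(0.5, 0.5 - d, 0.5 + d)
    expect_equal(spec$shape1, spec$shape2, tolerance = 1e-12)
  }
})

test_that("infeasible or malformed beta requests are rejected at construction", {
  # implied variance exceeds mean*(1-mean)
  expect_error(beta_from_mean_range(0.02, 0.001, 0.9), "infeasible")
  expect_error(beta_from_mean_range(0.5, 0.6, 0.4), "lower <= mean <= upper")
  expect_error(beta_from_mean_range(1.2, 1.1, 1.3), "< 1")
})

test_that("gamma fits match the cost rows and recover mean and sd", {
  spec <- gamma_from_mean_range(2648, 1986, 3310)  # ED-visit episode cost
  sd <- (3310 - 1986) / 3.92
  expect_equal(spec$shape, (2648 / sd)^2, tolerance = 1e-12)
  expect_equal(spec$scale, sd^2 / 2648, tolerance = 1e-12)
  expect_equal(spec$shape, 61.46560, tolerance = 1e-4)
  expect_equal(spec$scale, 43.081008, tolerance = 1e-4)
  expect_equal(dist_mean(spec), 2648, tolerance = 1e-9)
  expect_equal(dist_sd(spec), sd, tolerance = 1e-9)

  spec2 <- gamma_from_mean_range(230, 173, 288)    # hospitalization episode
  expect_equal(dist_mean(spec2), 230, tolerance = 1e-9)
  expect_equal(dist_sd(spec2), 29.336735, tolerance = 1e-4)

  expect_identical(gamma_from_mean_range(50, 50, 50)$family, "fixed")
  expect_error(gamma_from_mean_range(-3, -4, -2), "positive mean")
})

test_that("every packaged range is fitted mean-exact and sd-exact", {
  d <- parameter_distributions(base_params)
  cd <- base_params$econ$cycle_days
  targets <- list(
    rr_exacerbation = base_params$effect$rr_exacerbation,
    utility_controlled = base_params$utilities$controlled,
    decrement_ocs = base_params$utilities$decrement_ocs,
    decrement_ed = base_params$utilities$decrement_ed,
    decrement_hosp = base_params$utilities$decrement_hosp,
    discontinuation = base_params$adherence$discontinuation,
    cost_drug = base_params$costs$drug_per_4wk,
    cost_controlled = base_params$costs$controlled_state_annual,
    cost_ocs = base_params$costs$ocs_burst_per_episode,
    cost_ed = base_params$costs$ed_visit_per_episode,
    cost_hosp = base_params$costs$hospitalization_per_episode)
  for (nm in names(targets)) {
    pr <- targets[[nm]]
    expect_equal(dist_mean(d[[nm]]), pr$base, tolerance = 1e-9)
    expect_equal(dist_sd(d[[nm]]), (pr$upper - pr$lower) / 3.92,
                 tolerance = 1e-9)
  }
  # the annual rate is fitted on the per-cycle probability scale
  p3 <- rate_to_cycle_probability(
    c(base_params$events$exacerbation_annual_rate$base,
      base_params$events$exacerbation_annual_rate$lower,
      base_params$events$exacerbation_annual_rate$upper), cd)
  expect_equal(dist_mean(d$p_exacerbation_cycle), p3[1], tolerance = 1e-9)
  expect_equal(dist_sd(d$p_exacerbation_cycle), (p3[3] - p3[2]) / 3.92,
               tolerance = 1e-9)
})

test_that("the packaged parameter set passes validation; violations are data", {
  expect_identical(nrow(validate_parameter_set(base_params)), 0L)

  p <- base_params
  p$utilities$controlled$base <- 1.2
  p$utilities$controlled$upper <- 1.3
  v <- validate_parameter_set(p)
  expect_true(any(grepl("utilities.controlled", v$field, fixed = TRUE)))

  p2 <- base_params
  p2$costs$drug_per_4wk <- structure(list(base = -5, lower = -5, upper = -5),
                                     class = "point_range")
  v2 <- validate_parameter_set(p2)
  expect_true(any(v2$field == "costs.drug_per_4wk"))
})

test_that("loading honours overrides and rejects invariant violations", {
  p <- load_parameter_set(list(econ = list(annual_discount_rate =
    list(base = 0, lower = 0, upper = 0))))
  expect_identical(p$econ$annual_discount_rate$base, 0)

  expect_error(
    load_parameter_set(list(events = list(split_ocs = 0.3, split_ed = 0.35,
                                          split_hosp = 0.25))),
    "split")

  # file-based override round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("effect:\n  rr_exacerbation: {base: 0.8, lower: 0.7, upper: 0.9}",
             f)
  expect_identical(load_parameter_set(f)$effect$rr_exacerbation$base, 0.8)
})

test_that("sampling is seed-deterministic and respects distribution support", {
  set.seed(11); a <- sample_parameter_set(base_params)
  set.seed(11); b <- sample_parameter_set(base_params)
  expect_identical(a, b)
  expect_true(a$effect$rr_exacerbation$base > 0 &&
                a$effect$rr_exacerbation$base < 1)
  expect_true(a$utilities$controlled$base > 0 &&
                a$utilities$controlled$base < 1)
  expect_true(all(vapply(a$costs, function(x) x$base > 0, logical(1))))
  # ranges stay untouched
  expect_identical(a$effect$rr_exacerbation[c("lower", "upper")],
                   base_params$effect$rr_exacerbation[c("lower", "upper")])
})

test_that("degenerate ranges sample to the base case exactly", {
  set.seed(3)
  s <- sample_parameter_set(degenerate_params())
  expect_equal(s$effect$rr_exacerbation$base, 0.72, tolerance = 1e-12)
  expect_equal(s$costs$ed_visit_per_episode$base, 2648, tolerance = 1e-12)
  expect_equal(s$events$exacerbation_annual_rate$base, 1.14,
               tolerance = 1e-12)
})

test_that("sampled means converge to the base values (mean-preserving fits)", {
  set.seed(19)
  n <- 5000
  d <- draw_parameters(base_params, n)
  checks <- list(
    c("rr_exacerbation", 0.72, (0.83 - 0.62) / 3.92),
    c("utility_controlled", 0.74, (0.93 - 0.56) / 3.92),
    c("cost_ed", 2648, (3310 - 1986) / 3.92),
    c("discontinuation", 0.28, (0.43 - 0.24) / 3.92))
  for (cs in checks) {
    se <- as.numeric(cs[3]) / sqrt(n)
    expect_lt(abs(mean(d[[cs[1]]]) - as.numeric(cs[2])), 3 * se)
  }
  # rate draws are mean-preserving on the per-cycle probability scale
  p <- rate_to_cycle_probability(d$exacerbation_annual_rate, 14)
  p0 <- rate_to_cycle_probability(1.14, 14)
  se_p <- dist_sd(parameter_distributions(base_params)$p_exacerbation_cycle) /
    sqrt(n)
  expect_lt(abs(mean(p) - p0), 3 * se_p)
})

test_that("a relative risk reaching 1 falls back to a log-normal fit", {
  p <- set_param(base_params, "effect", "rr_exacerbation", 1.1, 0.9, 1.3)
  expect_warning(d <- parameter_distributions(p), "log-normal")
  expect_identical(d$rr_exacerbation$family, "lnorm")
  expect_equal(dist_mean(d$rr_exacerbation), 1.1, tolerance = 1e-9)
})
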