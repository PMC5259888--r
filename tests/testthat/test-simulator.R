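test_that("prevalence propagation honours its boundary cases", {
  # no incidence, proportional attrition: prevalence unchanged
  expect_equal(propagate_prevalence(0.07, hazard = 0, SP = 0.9, SN = 0.9), 0.07)
  # no incidence, all positives die
  expect_equal(propagate_prevalence(0.07, hazard = 0, SP = 0, SN = 0.95), 0)
  # nobody to convert, nobody positive
  expect_equal(propagate_prevalence(0, hazard = 0, SP = 0.8, SN = 0.9), 0)
  # frozen value at the canonical parameters (m = 1000)
  expect_equal(
    propagate_prevalence(0.05, 0.02, SP = 0.81, SN = 0.98, T_years = 2,
                         m_substeps = 1000),
    0.07614047, tolerance = 1e-7
  )
  expect_error(propagate_prevalence(0.05, -0.1, 0.9, 0.9), "hazard")
})

test_that("the discrete propagator converges to the continuous-time compartment model", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(p0 = c(0, 0.05, 0.2), h = c(0.005, 0.05),
                      SP = c(0.81, 0.95), SN = c(0.9, 0.99))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ode <- ode_prevalence(g$p0, g$h, g$SP, g$SN, 2)
    coarse <- propagate_prevalence(g$p0, g$h, g$SP, g$SN, 2, m_substeps = 10)
    fine <- propagate_prevalence(g$p0, g$h, g$SP, g$SN, 2, m_substeps = 2000)
    expect_lt(abs(fine - ode), abs(coarse - ode) + 1e-12)
    expect_lt(abs(fine - ode), 5e-5)
  }
})

test_that("the estimator recovers the hazard up to the survivor-attrition factor", {
  # Feeding propagated prevalence back through incidence() under-recovers the
  # hazard by the analytic attrition factor logmean(SP, SN) / ((1 + SN) / 2)
  # (converts die before the second survey but their person-years count).
  grid <- expand.grid(p0 = c(0.02, 0.1), h = c(0.002, 0.01, 0.05),
                      SP = c(0.78, 0.85, 0.92, 0.97), SN = c(0.92, 0.99))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pT <- propagate_prevalence(g$p0, g$h, g$SP, g$SN, 2, m_substeps = 1000)
    est <- incidence(g$p0, pT, g$SP, g$SN, 2)$rate
    ratio <- est / g$h
    expect_lte(ratio, 1 + 1e-9)
    expect_equal(ratio, attrition_factor(g$SP, g$SN), tolerance = 0.025)
  }
  # the under-recovery vanishes as survival approaches 1
  pT <- propagate_prevalence(0.05, 0.01, 0.999, 0.9995, 2, 1000)
  expect_equal(incidence(0.05, pT, 0.999, 0.9995, 2)$rate, 0.01,
               tolerance = 1e-3)
})

test_that("survey generation is deterministic in expectation and reproducible under sampling", {
  sc <- default_scenario(n_waves = 3)
  waves <- generate_surveys(sc)
  expect_length(waves, 3)
  expect_equal(attr(waves[[1]], "wave_start_year"), 2000)
  expect_equal(attr(waves[[3]], "wave_start_year"), 2004)
  # second wave equals one propagation of the first
  expect_equal(
    waves[[2]]$p,
    propagate_prevalence(waves[[1]]$p, sc$strata$hazard, sc$strata$SP,
                         sc$strata$SN, sc$T_years, sc$m_substeps)
  )

  sb <- default_scenario(n_waves = 3, mode = "binomial", seed = 99)
  w1 <- generate_surveys(sb)
  w2 <- generate_surveys(sb)
  expect_identical(w1, w2)
  sb2 <- default_scenario(n_waves = 3, mode = "binomial", seed = 100)
  expect_false(identical(generate_surveys(sb2), w1))

  # law of large numbers: binomial tables approach the expected-value tables
  big <- default_scenario(n_waves = 2, mode = "binomial", seed = 3,
                          n_per_stratum = 1e6)
  exp_tables <- generate_surveys(default_scenario(n_waves = 2))
  big_tables <- generate_surveys(big)
  for (w in 1:2) {
    expect_lt(max(abs(big_tables[[w]]$p - exp_tables[[w]]$p)), 1e-3)
  }
})

test_that("zero hazard yields a numerically null standardized incidence", {
  sc <- default_scenario(n_waves = 3)
  sc$strata$hazard <- 0
  waves <- generate_surveys(sc)
  est <- estimate_wave_pair(waves[[1]], waves[[2]], scenario_survival(sc))
  std <- direct_standardize(est, default_standard_population(), min_age = 35)
  expect_lt(abs(std$rate_per_100000 / 1e5), 1e-12)
})

test_that("estimated incidence increases strictly with the true hazard", {
  base <- default_scenario(n_waves = 2)
  std <- default_standard_population()
  rates <- vapply(c(0.5, 1, 2, 4), function(mult) {
    sc <- base
    sc$strata$hazard <- sc$strata$hazard * mult
    waves <- generate_surveys(sc)
    est <- estimate_wave_pair(waves[[1]], waves[[2]], scenario_survival(sc))
    direct_standardize(est, std, min_age = 35)$rate_per_100000
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the full pipeline recovers scenario truth up to the predicted attrition", {
  sc <- default_scenario(n_waves = 4)
  std <- default_standard_population()
  report <- run_estimate(generate_surveys(sc), scenario_survival(sc), std,
                         min_age = 35)
  truth <- scenario_true_incidence(sc, std, min_age = 35)
  ratio <- report$standardized$rate_per_100000 / truth
  expect_true(all(ratio > 0.90 & ratio <= 1))
  # and the attrition-weighted analytic prediction pins the ratio to ~1%
  st <- sc$strata
  w <- default_standard_population()$count
  predicted <- sum(w * st$hazard * attrition_factor(st$SP, st$SN)) /
    sum(w * st$hazard)
  expect_equal(ratio, rep(predicted, length(ratio)), tolerance = 0.015)
})

test_that("Poisson intervals achieve nominal coverage in the event-count regime", {
  # Coverage is assessed where the Poisson model holds: incidence measured
  # from an initially disease-free stratum (p0 = 0), so the only randomness
  # is the event count; truth is the expected-value-mode estimate.
  h <- 0.01; SP <- 0.9; SN <- 0.98; n <- 5000
  pT_exp <- propagate_prevalence(0, h, SP, SN, 2, 100)
  truth <- incidence(0, pT_exp, SP, SN, 2)$rate
  set.seed(7)
  covered <- replicate(300, {
    pT_obs <- rbinom(1, n, pT_exp) / n
    est <- incidence(0, pT_obs, SP, SN, 2)
    ci <- poisson_ci(max(est$rate, 0), est$person_years_per_respondent, n)
    ci$ci_lo <= truth && truth <= ci$ci_hi
  })
  expect_gte(mean(covered), 0.90)
})
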