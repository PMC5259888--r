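test_that("cohort factor matches direct arithmetic and collapses at the boundaries", {
  expect_equal(cohort_factor(0, SP = 0.5, SN = 0.98), 0.98)
  expect_equal(cohort_factor(1, SP = 0.9, SN = 0.5), 0.9)
  expect_equal(cohort_factor(0.2, SP = 0.9, SN = 0.99), 0.972)
  # two algebraic forms agree
  p <- c(0, 0.1, 0.5, 1)
  expect_equal(cohort_factor(p, 0.8, 0.95), 0.8 * p + 0.95 * (1 - p))
  expect_error(cohort_factor(1.2, 0.9, 0.9), "p0")
  expect_error(cohort_factor(0.5, -0.1, 0.9), "SP")
  expect_error(cohort_factor(0.5, 0.9, 1.5), "SN")
})

test_that("cohort factor stays within the survival envelope", {
  set.seed(11)
  for (i in 1:200) {
    p0 <- runif(1); SP <- runif(1); SN <- runif(1)
    f <- cohort_factor(p0, SP, SN)
    expect_gte(f, min(SP, SN) - 1e-12)
    expect_lte(f, max(SP, SN) + 1e-12)
  }
})

test_that("incidence reproduces hand-computed rates and null cases", {
  est <- incidence(p0 = 0, pT = 0.1, SP = 0.7, SN = 1, T_years = 2)
  expect_equal(est$rate, 0.1 / 1.9, tolerance = 1e-12)
  expect_equal(est$person_years_per_respondent, (1 + 0.9) * 2 / 2)
  expect_false(est$negative_flag)

  # numerator vanishes when F*pT = SP*p0
  p0 <- 0.1; SP <- 0.8; SN <- 0.99
  F <- cohort_factor(p0, SP, SN)
  pT <- SP * p0 / F
  expect_equal(incidence(p0, pT, SP, SN, 2)$rate, 0, tolerance = 1e-15)

  # no deaths, no prevalence change: exactly zero
  est0 <- incidence(0.05, 0.05, SP = 1, SN = 1, T_years = 2)
  expect_identical(est0$rate, 0)
  expect_false(est0$negative_flag)
})

test_that("negative rates are preserved raw and flagged exactly when F*pT < SP*p0", {
  set.seed(23)
  for (i in 1:200) {
    p0 <- runif(1, 0, 0.5); pT <- runif(1, 0, 0.5)
    SP <- runif(1, 0.5, 1); SN <- runif(1, 0.8, 1)
    est <- incidence(p0, pT, SP, SN, 2)
    F <- cohort_factor(p0, SP, SN)
    expect_identical(est$negative_flag, F * pT < SP * p0)
    expect_identical(est$negative_flag, est$rate < 0)
  }
  # a concrete prevalence drop: raw negative value, never floored
  est <- incidence(0.2, 0.1, SP = 0.95, SN = 0.99, T_years = 2)
  expect_lt(est$rate, 0)
  expect_true(est$negative_flag)
})

test_that("incidence refuses a degenerate stratum with no person-years", {
  expect_error(incidence(1, 1, SP = 0.9, SN = 0.9, T_years = 2), "degenerate")
})

test_that("Poisson limits are exact Garwood limits", {
  # 10 implied events over 1000 person-years at 95%
  ci <- poisson_ci(rate = 10 / 1000, person_years = 2, n = 500, level = 0.95)
  expect_equal(ci$implied_events, 10)
  expect_equal(ci$ci_lo, 0.004795389, tolerance = 1e-6)
  expect_equal(ci$ci_hi, 0.018390356, tolerance = 1e-6)
  # independent route: exact limits invert the Poisson tail probabilities
  expect_equal(1 - ppois(9, ci$ci_lo * 1000), 0.025, tolerance = 1e-9)
  expect_equal(ppois(10, ci$ci_hi * 1000), 0.025, tolerance = 1e-9)

  # zero-count lower bound is zero
  ci0 <- poisson_ci(rate = 0, person_years = 2, n = 500)
  expect_identical(ci0$ci_lo, 0)
  expect_gt(ci0$ci_hi, 0)

  expect_error(poisson_ci(-0.01, 2, 500), "negative_flag")
  expect_error(poisson_ci(0.01, 2, 0), "'n'")
  expect_error(poisson_ci(0.01, 2, 500, level = 1), "level")
})

test_that("wave-pair estimation joins strata and delegates to the scalar core", {
  prev0 <- make_prev(c(0, 0.02, 0.05), n = 1200, year = 1999)
  prevT <- make_prev(c(0.01, 0.03, 0.06), n = 1100, year = 2001)
  surv <- make_surv(SP = c(0.95, 0.9, 0.85), SN = c(0.99, 0.98, 0.96))
  est <- estimate_wave_pair(prev0, prevT, surv)
  expect_equal(nrow(est), 3)
  direct <- incidence(prev0$p, prevT$p, surv$SP, surv$SN, 2)
  expect_equal(est$rate, direct$rate)
  # interval dating: two-year waves starting 1999 and 2001
  expect_equal(unique(est$interval_start), as.Date("2000-01-01"))
  expect_equal(unique(est$interval_end), as.Date("2002-01-01"))
  # CIs bracket the point estimate where computed
  ok <- !is.na(est$ci_lo)
  expect_true(all(est$ci_lo[ok] <= est$rate[ok] + 1e-12))
  expect_true(all(est$rate[ok] <= est$ci_hi[ok] + 1e-12))

  # single-stratum delegation example
  one <- estimate_wave_pair(make_prev(0), make_prev(0.1),
                            make_surv(0.7, 1))
  expect_equal(one$rate, 0.1 / 1.9, tolerance = 1e-12)
})

test_that("wave-pair estimation enforces its contracts", {
  empty <- make_prev(numeric(0))
  expect_equal(nrow(estimate_wave_pair(empty, empty, make_surv(numeric(0), numeric(0)))), 0)

  prev0 <- make_prev(c(0.02, 0.05))
  prevT <- make_prev(c(0.03, 0.06))
  surv <- make_surv(c(0.9, 0.85), c(0.98, 0.96))
  short <- prevT[-1, , drop = FALSE]
  expect_error(estimate_wave_pair(prev0, short, surv), "missing from 'prevT'")
  expect_error(estimate_wave_pair(prev0, prevT, surv[-2, , drop = FALSE]),
               "missing from 'surv'")
  # wave spacing must match the survival interval
  expect_error(
    estimate_wave_pair(prev0, prevT, surv, year0 = 1999, yearT = 2003),
    "does not match the survival interval"
  )
})
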