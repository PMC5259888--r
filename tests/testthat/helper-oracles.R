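# Independent oracles and small fixture builders used across the suite.

# Analytic small-hazard attrition factor of the closed-form estimator: the
# estimator counts only converts who survive to the second survey, so in the
# small-h limit the recovered rate is the true hazard times
#   logmean(SP, SN) / ((1 + SN) / 2),
# the logarithmic mean of the two survival fractions (average survival of a
# convert from conversion to the survey, under exponential mortality) over
# the trapezoidal person-year factor. Derived by integrating
# h * N(t) * SP^((T-t)/T) with N(t) = N0 * SN^(t/T).
attrition_factor <- function(SP, SN) {
  lm_ <- ifelse(abs(SP - SN) < 1e-12, SP, (SN - SP) / log(SN / SP))
  lm_ / ((1 + SN) / 2)
}

# Continuous-time two-compartment oracle via deSolve: positives die at rate
# -log(SP)/T, negatives die at -log(SN)/T and convert at rate h.
ode_prevalence <- function(p0, hazard, SP, SN, T_years) {
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      dP <- -muP * y[1] + h * y[2]
      dN <- -(muN + h) * y[2]
      list(c(dP, dN))
    })
  }
  parms <- c(muP = -log(SP) / T_years, muN = -log(SN) / T_years, h = hazard)
  out <- deSolve::ode(y = c(P = p0, N = 1 - p0), times = c(0, T_years),
                      func = rhs, parms = parms, rtol = 1e-10, atol = 1e-12)
  P <- out[2, "P"]; N <- out[2, "N"]
  unname(P / (P + N))
}

# One-sex stratified table builders.
make_strata <- function(n = 3, sex = "f") {
  lo <- 35 + 5 * (seq_len(n) - 1)
  hi <- lo + 5
  if (n > 0) hi[n] <- Inf
  data.frame(sex = rep(sex, n), age_lo = lo, age_hi = hi)
}

# reorder a generated wave's prevalences to another table's sex/age ordering
order_strata_like <- function(wave, template) {
  key_w <- paste(wave$sex, wave$age_lo)
  key_t <- paste(template$sex, template$age_lo)
  wave$p[match(key_t, key_w)]
}

make_prev <- function(p, n = NULL, sex = "f", year = NULL) {
  tb <- make_strata(length(p), sex)
  tb$p <- p
  if (!is.null(n)) tb$n <- rep_len(n, length(p))
  if (!is.null(year)) attr(tb, "wave_start_year") <- year
  tb
}

make_surv <- function(SP, SN, T_years = 2, sex = "f") {
  tb <- make_strata(length(SP), sex)
  tb$SP <- SP
  tb$SN <- SN
  tb$T <- rep_len(T_years, length(SP))
  tb
}
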