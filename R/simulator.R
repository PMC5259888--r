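#' Define a synthetic open-population scenario
#'
#' A scenario fixes, per stratum, a true constant incidence hazard, an initial
#' prevalence and the two-survey survival fractions of disease-positive and
#' disease-negative people, plus the survey design (interval length, number
#' of waves, deterministic or binomial sampling). Generated surveys feed the
#' estimator, so parameter recovery can be checked against known truth
#' without any external data.
#'
#' @param strata Data.frame with columns `sex`, `age_lo`, `age_hi`, `hazard`
#'   (events per person-year among the disease-free), `p_init`, `SP`, `SN`.
#' @param T_years Inter-survey interval in years.
#' @param n_waves Number of surveys (>= 2).
#' @param mode `"expected_value"` (deterministic prevalences) or `"binomial"`
#'   (each wave samples `n_per_stratum` fresh respondents per stratum).
#' @param n_per_stratum Respondents per stratum per wave (binomial mode; also
#'   recorded as `n` in expected-value tables for CI computation).
#' @param seed Integer seed for binomial sampling.
#' @param m_substeps Sub-steps per interval in the forward propagation.
#' @param start_year First calendar year of the first wave.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(strata, T_years = 2, n_waves = 2,
                         mode = c("expected_value", "binomial"),
                         n_per_stratum = 5000, seed = 1L, m_substeps = 100,
                         start_year = 2000) {
  mode <- match.arg(mode)
  check_stratum_frame(strata, "strata")
  need <- c("hazard", "p_init", "SP", "SN")
  miss <- setdiff(need, names(strata))
  if (length(miss) > 0) {
    stop(sprintf("scenario strata missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(strata$hazard < 0)) stop("hazards must be >= 0", call. = FALSE)
  check_proportion(strata$p_init, "p_init")
  check_proportion(strata$SP, "SP")
  check_proportion(strata$SN, "SN")
  if (n_waves < 2) stop("'n_waves' must be >= 2", call. = FALSE)
  if (T_years <= 0) stop("'T_years' must be positive", call. = FALSE)
  if (m_substeps < 1) stop("'m_substeps' must be >= 1", call. = FALSE)
  structure(
    list(strata = order_strata(strata), T_years = T_years, n_waves = n_waves,
         mode = mode, n_per_stratum = n_per_stratum, seed = as.integer(seed),
         m_substeps = m_substeps, start_year = start_year),
    class = "sim_scenario"
  )
}

#' Default synthetic scenario: an adult CVD-like open population
#'
#' Two sexes by five age bands (35+), with incidence hazards rising from
#' 0.0015 to 0.024 per person-year, two-year disease-positive survival
#' falling from 0.96 to 0.78-0.79 and disease-negative survival from 0.997
#' to 0.90-0.92 with age, and initial prevalence between 1.5% and 20%.
#' Magnitudes follow typical published case-fatality and vital-statistics
#' figures for myocardial infarction / broad heart disease in North American
#' adults.
#'
#' @inheritParams sim_scenario
#' @param ... Passed through to [sim_scenario()].
#' @return A `sim_scenario` object.
#' @seealso [default_standard_population()] for the matching census-like
#'   weights.
#' @export
default_scenario <- function(n_waves = 4, mode = "expected_value", ...) {
  bands_lo <- c(35, 45, 55, 65, 75)
  bands_hi <- c(45, 55, 65, 75, Inf)
  strata <- rbind(
    data.frame(sex = "male", age_lo = bands_lo, age_hi = bands_hi,
               hazard = c(0.003, 0.006, 0.010, 0.016, 0.024),
               p_init = c(0.030, 0.060, 0.100, 0.150, 0.200),
               SP = c(0.95, 0.93, 0.90, 0.85, 0.78),
               SN = c(0.996, 0.993, 0.985, 0.965, 0.900)),
    data.frame(sex = "female", age_lo = bands_lo, age_hi = bands_hi,
               hazard = c(0.0015, 0.003, 0.006, 0.011, 0.018),
               p_init = c(0.015, 0.030, 0.060, 0.100, 0.160),
               SP = c(0.96, 0.94, 0.91, 0.86, 0.79),
               SN = c(0.997, 0.995, 0.988, 0.972, 0.920))
  )
  sim_scenario(strata, n_waves = n_waves, mode = mode, ...)
}

#' Census-like standard population for the default scenario
#'
#' Stratum counts (thousands of persons) with the age profile of a North
#' American census population aged 35 and over.
#'
#' @return Data.frame with columns `sex`, `age_lo`, `age_hi`, `count`.
#' @export
default_standard_population <- function() {
  bands_lo <- c(35, 45, 55, 65, 75)
  bands_hi <- c(45, 55, 65, 75, Inf)
  rbind(
    data.frame(sex = "male", age_lo = bands_lo, age_hi = bands_hi,
               count = c(22000, 19000, 13000, 9000, 6000)),
    data.frame(sex = "female", age_lo = bands_lo, age_hi = bands_hi,
               count = c(22500, 19800, 14000, 10500, 9000))
  )
}

#' Propagate prevalence forward through one survey interval
#'
#' Deterministic two-compartment bookkeeping: the interval of length
#' `T_years` is split into `m_substeps` sub-steps; in each, positives survive
#' with probability `SP^(1/m)`, negatives survive with probability
#' `SN^(1/m)` and then convert with probability `1 - exp(-hazard * T/m)`
#' (survive first, then convert). Returns the end-of-interval prevalence
#' among survivors. This propagation is the independent forward model the
#' estimator is validated against.
#'
#' @param p Starting prevalence proportion(s).
#' @param hazard Constant conversion hazard(s), events per person-year.
#' @param SP,SN Whole-interval survival fractions of positives / negatives.
#' @param T_years Interval length in years.
#' @param m_substeps Number of sub-steps (>= 1).
#' @return End-of-interval prevalence proportion(s).
#' @examples
#' propagate_prevalence(0.05, hazard = 0.02, SP = 0.81, SN = 0.98)
#' @export
propagate_prevalence <- function(p, hazard, SP, SN, T_years = 2,
                                 m_substeps = 100) {
  check_proportion(p, "p")
  check_proportion(SP, "SP")
  check_proportion(SN, "SN")
  if (any(hazard < 0)) stop("'hazard' must be >= 0", call. = FALSE)
  if (m_substeps < 1) stop("'m_substeps' must be >= 1", call. = FALSE)
  P <- p
  N <- 1 - p
  sp_m <- SP^(1 / m_substeps)
  sn_m <- SN^(1 / m_substeps)
  conv <- 1 - exp(-hazard * T_years / m_substeps)
  for (k in seq_len(m_substeps)) {
    P <- P * sp_m
    N <- N * sn_m
    new_cases <- N * conv
    P <- P + new_cases
    N <- N - new_cases
  }
  alive <- P + N
  out <- ifelse(alive > 0, P / alive, 0)
  unname(out)
}

#' Generate successive cross-sectional prevalence surveys
#'
#' Propagates each stratum's prevalence wave-to-wave with
#' [propagate_prevalence()]. In `expected_value` mode the tables carry the
#' deterministic prevalences; in `binomial` mode each wave draws
#' `n_per_stratum` fresh respondents per stratum (repeated cross-sections)
#' with the scenario seed, so output is reproducible.
#'
#' @param scenario A `sim_scenario` object.
#' @return A list of `n_waves` prevalence tables (columns `sex`, `age_lo`,
#'   `age_hi`, `p`, `n`), each with a `wave_start_year` attribute; names are
#'   `wave_<year>`.
#' @export
generate_surveys <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  st <- scenario$strata
  p_exp <- st$p_init
  waves <- vector("list", scenario$n_waves)
  if (scenario$mode == "binomial") set.seed(scenario$seed)
  for (w in seq_len(scenario$n_waves)) {
    if (w > 1) {
      p_exp <- propagate_prevalence(p_exp, st$hazard, st$SP, st$SN,
                                    scenario$T_years, scenario$m_substeps)
    }
    p_obs <- if (scenario$mode == "binomial") {
      stats::rbinom(length(p_exp), scenario$n_per_stratum, p_exp) /
        scenario$n_per_stratum
    } else {
      p_exp
    }
    tb <- data.frame(sex = st$sex, age_lo = st$age_lo, age_hi = st$age_hi,
                     p = p_obs, n = scenario$n_per_stratum)
    attr(tb, "wave_start_year") <-
      scenario$start_year + (w - 1) * scenario$T_years
    waves[[w]] <- tb
  }
  names(waves) <- sprintf("wave_%d", scenario$start_year +
                            (seq_len(scenario$n_waves) - 1) * scenario$T_years)
  waves
}

#' Survival table implied by a scenario
#'
#' The `SP`/`SN`/`T` table the estimator should be given when analysing the
#' scenario's surveys (the simulator and the estimator share the same
#' constancy assumption).
#'
#' @param scenario A `sim_scenario` object.
#' @return Data.frame with columns `sex`, `age_lo`, `age_hi`, `SP`, `SN`, `T`.
#' @export
scenario_survival <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  st <- scenario$strata
  data.frame(sex = st$sex, age_lo = st$age_lo, age_hi = st$age_hi,
             SP = st$SP, SN = st$SN, T = scenario$T_years)
}

#' True standardized incidence of a scenario
#'
#' The standard-population-weighted mean of the scenario's per-stratum
#' hazards, per 100,000 person-years - the ground truth the full pipeline
#' should recover.
#'
#' @param scenario A `sim_scenario` object.
#' @param std Standard population (columns `sex`, `age_lo`, `age_hi`,
#'   `count`).
#' @param min_age Optional lower age cut, as in [direct_standardize()].
#' @return True standardized incidence per 100,000 person-years.
#' @export
scenario_true_incidence <- function(scenario, std, min_age = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  rates <- scenario$strata
  rates$rate <- rates$hazard
  direct_standardize(rates, std, min_age)$rate_per_100000
}
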