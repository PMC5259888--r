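#' Cohort-size factor over a survey interval
#'
#' The expected fraction of a stratum cohort alive at the end of the
#' inter-survey interval, given baseline prevalence and the differential
#' two-survey survival of disease-positive and disease-negative people:
#' \deqn{F = 1 - (1 - SP)\,p_0 - (1 - SN)(1 - p_0) = SP\,p_0 + SN(1 - p_0).}
#' It is the survival-weighted mixture of the two compartments and therefore
#' always lies between `min(SP, SN)` and `max(SP, SN)`.
#'
#' @param p0 Baseline prevalence proportion(s) in \[0, 1\].
#' @param SP Survival fraction of disease-positive people over the interval.
#' @param SN Survival fraction of disease-negative people over the interval.
#' @return Numeric vector of cohort-size factors.
#' @seealso [incidence()] which consumes this factor.
#' @examples
#' cohort_factor(0.2, SP = 0.9, SN = 0.99)  # 0.972
#' @export
cohort_factor <- function(p0, SP, SN) {
  check_proportion(p0, "p0")
  check_proportion(SP, "SP")
  check_proportion(SN, "SN")
  1 - (1 - SP) * p0 - (1 - SN) * (1 - p0)
}

#' Per-stratum incidence from two successive prevalence surveys
#'
#' Closed-form prevalence-to-incidence conversion for an irreversible
#' condition. New cases observed at the second survey are the disease-positive
#' people at time T in excess of the surviving baseline positives,
#' `F * pT - SP * p0`; person-years at risk per baseline respondent are
#' approximated by the trapezoid of the disease-negative fraction,
#' `T * (1 - p0 + F * (1 - pT)) / 2`. The rate is their ratio:
#' \deqn{I \approx \frac{2 (F p_T - SP\, p_0)}{T (1 - p_0 + F (1 - p_T))}.}
#'
#' A negative rate (prevalence falling faster than mortality attrition can
#' explain) is reported raw and flagged via `negative_flag`, never floored:
#' downstream standardization must consume the raw value to stay unbiased.
#'
#' @inheritParams cohort_factor
#' @param pT Prevalence proportion(s) at the second survey.
#' @param T_years Inter-survey interval in years (default 2).
#' @return A data.frame with one row per input element and columns `rate`
#'   (events per person-year), `person_years_per_respondent`, and
#'   `negative_flag`.
#' @examples
#' incidence(p0 = 0, pT = 0.1, SP = 0.7, SN = 1, T_years = 2)  # 0.1/1.9
#' @export
incidence <- function(p0, pT, SP, SN, T_years = 2) {
  check_proportion(p0, "p0")
  check_proportion(pT, "pT")
  if (any(T_years <= 0)) stop("'T_years' must be positive", call. = FALSE)
  F <- cohort_factor(p0, SP, SN)
  denom <- T_years * (1 - p0 + F * (1 - pT))
  if (any(denom <= 0)) {
    stop("degenerate stratum: zero person-years (p0 = 1 with no surviving ",
         "disease-negative pool); incidence undefined", call. = FALSE)
  }
  num <- 2 * (F * pT - SP * p0)
  rate <- num / denom
  data.frame(
    rate = rate,
    person_years_per_respondent = denom / 2,
    negative_flag = F * pT < SP * p0
  )
}

#' Exact Poisson confidence limits for an incidence estimate
#'
#' Treats the implied event count `rate * n * person_years` as a Poisson
#' observation and returns exact (Garwood, chi-square based) limits on the
#' underlying rate, i.e. the count limits divided by total person-years.
#' The lower limit is 0 when the implied count is 0. The survey is treated as
#' a simple random sample; design effects are out of scope.
#'
#' @param rate Non-negative incidence rate (events per person-year).
#' @param person_years Person-years at risk per respondent (the incidence
#'   denominator divided by 2, as returned by [incidence()]).
#' @param n Respondent count in the stratum at the first survey.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A data.frame with columns `implied_events`, `ci_lo`, `ci_hi`
#'   (rates per person-year).
#' @examples
#' poisson_ci(rate = 0.01, person_years = 2, n = 500)
#' @export
poisson_ci <- function(rate, person_years, n, level = 0.95) {
  if (any(rate < 0)) {
    stop("confidence interval undefined for a negative rate; ",
         "inspect 'negative_flag' on the estimate", call. = FALSE)
  }
  if (any(n <= 0)) stop("'n' must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  py_total <- n * person_years
  x <- rate * py_total
  alpha <- 1 - level
  lo <- ifelse(x == 0, 0, stats::qchisq(alpha / 2, 2 * x) / 2 / py_total)
  hi <- stats::qchisq(1 - alpha / 2, 2 * x + 2) / 2 / py_total
  data.frame(implied_events = x, ci_lo = lo, ci_hi = hi)
}

#' Estimate incidence for every stratum of a wave pair
#'
#' Joins two prevalence tables and a survival table on the stratum key
#' (sex, age_lo, age_hi) and applies [incidence()] per stratum, attaching
#' Poisson confidence limits where a first-wave respondent count is available
#' and the estimate is non-negative. The three tables must cover an identical
#' stratum set; any mismatch raises a keyed error naming the missing strata.
#'
#' Estimation intervals follow the reference-year convention of two-year
#' survey cycles: an estimate from waves starting in 1999 and 2001 with
#' `wave_span = 2` is dated Jan 1, 2000 to Jan 1, 2002. Single-year waves use
#' `wave_span = 1`.
#'
#' @param prev0,prevT Prevalence tables (columns `sex`, `age_lo`, `age_hi`,
#'   `p`, optionally `n`), first and second survey. `wave_start_year` is taken
#'   from the `wave_start_year` attribute of each table unless given
#'   explicitly.
#' @param surv Survival table (columns `sex`, `age_lo`, `age_hi`, `SP`, `SN`,
#'   `T`).
#' @param year0,yearT First calendar year of each wave label (optional;
#'   default from table attributes).
#' @param wave_span Calendar years covered by one survey wave (2 for two-year
#'   cycles, 1 for single-year waves).
#' @param ci_level Confidence level for Poisson limits.
#' @return A data.frame with one row per stratum: the stratum key,
#'   `interval_start`/`interval_end` (Dates, when wave years are known),
#'   `p0`, `pT`, `rate`, `person_years_per_respondent`, `implied_events`,
#'   `ci_lo`, `ci_hi`, `negative_flag`. CI columns are `NA` where `n` is
#'   absent or the rate is negative.
#' @export
estimate_wave_pair <- function(prev0, prevT, surv,
                               year0 = attr(prev0, "wave_start_year"),
                               yearT = attr(prevT, "wave_start_year"),
                               wave_span = 2, ci_level = 0.95) {
  check_stratum_frame(prev0, "prev0")
  check_stratum_frame(prevT, "prevT")
  check_stratum_frame(surv, "surv")
  if (nrow(prev0) == 0 && nrow(prevT) == 0) {
    return(data.frame(
      sex = character(), age_lo = numeric(), age_hi = numeric(),
      p0 = numeric(), pT = numeric(), rate = numeric(),
      person_years_per_respondent = numeric(), implied_events = numeric(),
      ci_lo = numeric(), ci_hi = numeric(), negative_flag = logical()
    ))
  }
  check_strata_align(prev0, prevT, "prev0", "prevT")
  check_strata_align(prevT, prev0, "prevT", "prev0")
  check_strata_align(prev0, surv, "prev0", "surv")

  prev0 <- order_strata(prev0)
  key0 <- stratum_key(prev0)
  prevT <- prevT[match(key0, stratum_key(prevT)), , drop = FALSE]
  surv <- surv[match(key0, stratum_key(surv)), , drop = FALSE]

  T_years <- unique(surv$T)
  if (length(T_years) != 1) {
    stop("survival table must carry a single interval length 'T'",
         call. = FALSE)
  }
  if (!is.null(year0) && !is.null(yearT) && (yearT - year0) != T_years) {
    stop(sprintf(paste0("wave spacing (%s) does not match the survival ",
                        "interval T = %s"), yearT - year0, T_years),
         call. = FALSE)
  }

  est <- incidence(prev0$p, prevT$p, surv$SP, surv$SN, T_years)
  out <- data.frame(
    sex = prev0$sex, age_lo = prev0$age_lo, age_hi = prev0$age_hi,
    p0 = prev0$p, pT = prevT$p,
    rate = est$rate,
    person_years_per_respondent = est$person_years_per_respondent,
    implied_events = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    negative_flag = est$negative_flag
  )
  if (!is.null(year0)) {
    out$interval_start <- as.Date(sprintf("%d-01-01", year0 + wave_span - 1))
    out$interval_end <- as.Date(sprintf("%d-01-01",
                                        year0 + wave_span - 1 + T_years))
  }
  if ("n" %in% names(prev0)) {
    ok <- !is.na(prev0$n) & !out$negative_flag
    if (any(ok)) {
      ci <- poisson_ci(out$rate[ok], out$person_years_per_respondent[ok],
                       prev0$n[ok], ci_level)
      out$implied_events[ok] <- ci$implied_events
      out$ci_lo[ok] <- ci$ci_lo
      out$ci_hi[ok] <- ci$ci_hi
    }
  }
  rownames(out) <- NULL
  out
}
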