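#' Fraction of all events that are hospitalized
#'
#' Survey-based prevalence captures all events, including fatal (never
#' admitted alive) and silent (never recognized) ones, while surveillance
#' systems typically count hospitalized events only. Under independent fatal
#' and silent fractions the hospitalized share is the product of the
#' complements, `(1 - fatal_fraction) * (1 - silent_fraction)`.
#'
#' @param fatal_fraction Proportion of events that are fatal, in \[0, 1).
#' @param silent_fraction Proportion of events that are silent, in \[0, 1).
#' @return Hospitalized proportion.
#' @examples
#' hospitalized_fraction(0.30, 0.20)  # 0.56
#' @export
hospitalized_fraction <- function(fatal_fraction, silent_fraction) {
  check_proportion(fatal_fraction, "fatal_fraction")
  check_proportion(silent_fraction, "silent_fraction")
  if (any(fatal_fraction >= 1) || any(silent_fraction >= 1)) {
    stop("fatal and silent fractions must be < 1", call. = FALSE)
  }
  (1 - fatal_fraction) * (1 - silent_fraction)
}

#' Convert all-event incidence to hospitalized-event incidence
#'
#' Scales an incidence rate by [hospitalized_fraction()]. Being a scalar
#' multiple, the adjustment commutes with direct standardization.
#'
#' @param rate Incidence rate(s), any scale (typically per 100,000).
#' @param fatal_fraction,silent_fraction See [hospitalized_fraction()].
#' @return Adjusted rate(s) on the same scale; presentation rounding is the
#'   caller's concern.
#' @examples
#' adjust_incidence(843, 0.30, 0.20)  # 472.08
#' @export
adjust_incidence <- function(rate, fatal_fraction, silent_fraction) {
  if (any(!is.finite(rate))) stop("'rate' must be finite", call. = FALSE)
  rate * hospitalized_fraction(fatal_fraction, silent_fraction)
}

#' Fit a linear time trend to an incidence series
#'
#' Ordinary least squares of incidence (per 100,000) on calendar year minus a
#' reference year, so the intercept is the fitted rate at the reference year
#' and the slope the annual change. Requires at least three distinct years.
#'
#' @param year Calendar years (first year of each estimation interval label).
#' @param rate Incidence per 100,000 at those years (typically presented
#'   integer values).
#' @param reference_year Year at which the intercept is evaluated
#'   (default 2000).
#' @return An object of class `pi_trend`: list with `intercept`, `slope`,
#'   `reference_year`, `n`, `fitted`, `residuals`, `year`, `rate`.
#' @examples
#' fit_trend(c(2001, 2003, 2005, 2007, 2009), c(927, 779, 783, 873, 752))
#' @export
fit_trend <- function(year, rate, reference_year = 2000) {
  if (length(year) != length(rate)) {
    stop("'year' and 'rate' must have equal length", call. = FALSE)
  }
  if (length(unique(year)) < 3) {
    stop("trend fit needs at least 3 distinct years", call. = FALSE)
  }
  x <- year - reference_year
  fit <- stats::lm(rate ~ x)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      reference_year = reference_year,
      n = length(year),
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit)),
      year = year, rate = rate
    ),
    class = "pi_trend"
  )
}

#' @export
print.pi_trend <- function(x, digits = 0, ...) {
  cat(sprintf("Linear incidence trend (n = %d): rate = %s %s %s * (year - %d)\n",
              x$n, format(round(x$intercept, digits)),
              ifelse(x$slope < 0, "-", "+"),
              format(abs(round(x$slope, digits))), x$reference_year))
  invisible(x)
}

#' Annual percent decline implied by a fitted trend
#'
#' The fitted absolute slope as a percentage of the fitted rate at the
#' reference year: `100 * |slope| / intercept`.
#'
#' @param fit A `pi_trend` object from [fit_trend()].
#' @return Percent per year.
#' @export
annual_percent_decline <- function(fit) {
  stopifnot(inherits(fit, "pi_trend"))
  if (fit$intercept <= 0) {
    stop("annual percent decline undefined: fitted rate at the reference ",
         "year is not positive", call. = FALSE)
  }
  100 * abs(fit$slope) / fit$intercept
}

#' Projected percent reduction over a number of years
#'
#' Total percent change implied by the fitted line over `years` years,
#' relative to the fitted rate at the reference year:
#' `100 * years * |slope| / intercept`, capped at 100.
#'
#' @param fit A `pi_trend` object from [fit_trend()].
#' @param years Projection horizon in years (>= 0).
#' @return Percent reduction.
#' @export
percent_reduction <- function(fit, years) {
  stopifnot(inherits(fit, "pi_trend"))
  if (years < 0) stop("'years' must be non-negative", call. = FALSE)
  if (fit$intercept <= 0) {
    stop("percent reduction undefined: fitted rate at the reference year ",
         "is not positive", call. = FALSE)
  }
  min(100, 100 * years * abs(fit$slope) / fit$intercept)
}
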