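#' Substitute zero prevalence in young age bands
#'
#' Self-reported chronic-disease prevalence is often exactly zero in the
#' youngest survey strata, which would force a zero incidence estimate there.
#' Each zero is replaced by the first non-zero prevalence from the next-older
#' band of the same sex, scanning upward in age. Bands older than the last
#' non-zero band are left untouched; a sex whose bands are all zero stays all
#' zero, with a warning.
#'
#' @param prev Prevalence table (columns `sex`, `age_lo`, `age_hi`, `p`, ...),
#'   sorted by age within sex (re-sorted internally).
#' @return The table with zeros substituted, in sex/age order.
#' @examples
#' tb <- data.frame(sex = "f", age_lo = c(35, 40, 45, 50),
#'                  age_hi = c(40, 45, 50, 55), p = c(0, 0, 0.01, 0.02))
#' substitute_zero_prevalence(tb)$p  # 0.01 0.01 0.01 0.02
#' @export
substitute_zero_prevalence <- function(prev) {
  check_stratum_frame(prev, "prev")
  check_proportion(prev$p, "p")
  prev <- order_strata(prev)
  for (s in unique(prev$sex)) {
    idx <- which(prev$sex == s)
    p <- prev$p[idx]
    if (all(p == 0)) {
      warning(sprintf("all prevalences are zero for sex '%s'; nothing to substitute", s),
              call. = FALSE)
      next
    }
    for (i in seq_along(p)) {
      if (p[i] == 0) {
        donor <- which(p[(i + 1):length(p)] > 0)
        if (i < length(p) && length(donor) > 0) {
          p[i] <- p[i + donor[1]]
        }
      }
    }
    prev$p[idx] <- p
  }
  rownames(prev) <- NULL
  prev
}

#' Directly standardize stratum incidence rates
#'
#' Weighted mean of stratum-specific rates with weights proportional to a
#' standard (census) population's stratum counts, reported per 100,000
#' person-years. An optional minimum-age filter truncates the standard
#' population before weights are normalized (e.g. 35+ for an adult MI
#' analysis, 12+ for a broad heart-disease analysis). Every retained
#' standard-population stratum must have a matching rate; negative stratum
#' estimates enter as-is and are counted in `n_negative`.
#'
#' @param rates Data.frame of stratum estimates (columns `sex`, `age_lo`,
#'   `age_hi`, `rate`; typically from [estimate_wave_pair()]).
#' @param std Standard population (columns `sex`, `age_lo`, `age_hi`,
#'   `count`).
#' @param min_age Optional lower age cut applied to the standard population.
#' @return An object of class `pi_std_rate`: a list with
#'   `rate_per_100000` (full precision), `rate_rounded` (presentation value),
#'   `n_strata`, `n_negative`, and `label`.
#' @export
direct_standardize <- function(rates, std, min_age = NULL) {
  check_stratum_frame(rates, "rates")
  check_stratum_frame(std, "std")
  if (anyNA(std$count) || any(std$count < 0)) {
    stop("standard population counts must be non-negative", call. = FALSE)
  }
  label <- attr(std, "label")
  if (!is.null(min_age)) {
    std <- std[std$age_lo >= min_age, , drop = FALSE]
    if (nrow(std) == 0) {
      stop(sprintf("min_age = %s removes every standard-population stratum",
                   min_age), call. = FALSE)
    }
  }
  if (sum(std$count) <= 0) {
    stop("standard population has zero total count", call. = FALSE)
  }
  check_strata_align(std, rates, "standard population", "rates")
  m <- match(stratum_key(std), stratum_key(rates))
  r <- rates$rate[m]
  w <- std$count / sum(std$count)
  value <- sum(w * r) * 1e5
  structure(
    list(
      rate_per_100000 = value,
      rate_rounded = round(value),
      n_strata = nrow(std),
      n_negative = sum(r < 0),
      label = label
    ),
    class = "pi_std_rate"
  )
}

#' @export
print.pi_std_rate <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else sprintf(" [standard: %s]", x$label)
  cat(sprintf("Standardized incidence: %d per 100,000 person-years%s\n",
              x$rate_rounded, lab))
  cat(sprintf("  (%0.6g unrounded; %d strata, %d with negative estimates)\n",
              x$rate_per_100000, x$n_strata, x$n_negative))
  invisible(x)
}
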