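#' Run the full prevalence-to-incidence pipeline
#'
#' For each consecutive pair of prevalence waves: applies the
#' zero-prevalence substitution, estimates per-stratum incidence with
#' [estimate_wave_pair()], and directly standardizes to the supplied census
#' population. With three or more wave pairs a linear trend is fitted to the
#' presented (integer) standardized rates. When fatal/silent event fractions
#' are given, a hospitalized-incidence series and its trend are added.
#'
#' @param prevalence List of prevalence tables (data.frames from
#'   [read_prevalence_table()] or [generate_surveys()]) or character paths;
#'   at least 2, in chronological order.
#' @param survival Survival table (data.frame or path), columns `sex`,
#'   `age_lo`, `age_hi`, `SP`, `SN`, `T`.
#' @param standard_population Standard population (data.frame or path).
#' @param wave_start_years First calendar year of each wave label; default
#'   taken from `wave_start_year` attributes.
#' @param wave_span Calendar years covered by one wave (2 for two-year
#'   cycles, 1 for single-year waves); sets the interval dating and the
#'   trend x-coordinate.
#' @param min_age Optional lower age cut for standardization.
#' @param ci_level Confidence level for per-stratum Poisson intervals.
#' @param fatal_fraction,silent_fraction Optional event-adjustment fractions
#'   (see [hospitalized_fraction()]).
#' @param zero_substitution Apply [substitute_zero_prevalence()] per wave
#'   before pairing (default TRUE).
#' @param trend_reference_year Reference year for [fit_trend()]
#'   (default 2000).
#' @param output_dir Optional directory; when given, stratum estimates and
#'   the standardized series are written as CSV plus a plain-text summary.
#' @return An object of class `pi_report`: list with `stratum_estimates`
#'   (one row per stratum and wave pair), `standardized` (one row per wave
#'   pair: `year`, `interval`, `rate_per_100000`, `rate_rounded`,
#'   `n_negative`, and adjusted columns when applicable), `trend`,
#'   `adjusted_trend` (NULL when not computed), and `config`.
#' @export
run_estimate <- function(prevalence, survival, standard_population,
                         wave_start_years = NULL, wave_span = 2,
                         min_age = NULL, ci_level = 0.95,
                         fatal_fraction = NULL, silent_fraction = NULL,
                         zero_substitution = TRUE,
                         trend_reference_year = 2000, output_dir = NULL) {
  if (is.character(prevalence)) prevalence <- as.list(prevalence)
  if (!is.list(prevalence) || length(prevalence) < 2) {
    stop("need >= 2 prevalence waves to estimate incidence", call. = FALSE)
  }
  prevalence <- lapply(prevalence, function(p) {
    if (is.character(p)) read_prevalence_table(p) else p
  })
  if (is.character(survival)) survival <- read_survival_table(survival)
  if (is.character(standard_population)) {
    standard_population <- read_standard_population(standard_population)
  }
  if (is.null(wave_start_years)) {
    wave_start_years <- vapply(prevalence, function(p) {
      y <- attr(p, "wave_start_year")
      if (is.null(y)) NA_real_ else y
    }, numeric(1))
  }
  if (anyNA(wave_start_years) ||
      length(wave_start_years) != length(prevalence)) {
    stop("each wave needs a start year (attribute or 'wave_start_years')",
         call. = FALSE)
  }
  if (is.unsorted(wave_start_years, strictly = TRUE)) {
    stop("'wave_start_years' must be strictly increasing", call. = FALSE)
  }
  if (xor(is.null(fatal_fraction), is.null(silent_fraction))) {
    stop("supply both 'fatal_fraction' and 'silent_fraction', or neither",
         call. = FALSE)
  }
  adjust <- !is.null(fatal_fraction)

  if (zero_substitution) {
    prevalence <- lapply(prevalence, substitute_zero_prevalence)
  }

  n_pairs <- length(prevalence) - 1
  stratum_rows <- vector("list", n_pairs)
  std_rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    est <- estimate_wave_pair(
      prevalence[[i]], prevalence[[i + 1]], survival,
      year0 = wave_start_years[i], yearT = wave_start_years[i + 1],
      wave_span = wave_span, ci_level = ci_level
    )
    std <- direct_standardize(est, standard_population, min_age)
    year <- wave_start_years[i] + wave_span - 1
    interval <- sprintf("%d-%d", year, wave_start_years[i + 1] +
                          wave_span - 2)
    est$interval <- interval
    stratum_rows[[i]] <- est
    row <- data.frame(
      year = year, interval = interval,
      rate_per_100000 = std$rate_per_100000,
      rate_rounded = std$rate_rounded,
      n_negative = std$n_negative
    )
    if (adjust) {
      adj <- adjust_incidence(std$rate_per_100000, fatal_fraction,
                              silent_fraction)
      row$adjusted_per_100000 <- adj
      row$adjusted_rounded <- round(adj)
    }
    std_rows[[i]] <- row
  }
  standardized <- do.call(rbind, std_rows)
  rownames(standardized) <- NULL

  trend <- NULL
  adjusted_trend <- NULL
  if (n_pairs >= 3) {
    trend <- fit_trend(standardized$year, standardized$rate_rounded,
                       trend_reference_year)
    if (adjust) {
      adjusted_trend <- fit_trend(standardized$year,
                                  standardized$adjusted_rounded,
                                  trend_reference_year)
    }
  }

  report <- structure(
    list(
      stratum_estimates = do.call(rbind, stratum_rows),
      standardized = standardized,
      trend = trend,
      adjusted_trend = adjusted_trend,
      config = list(
        wave_start_years = wave_start_years, wave_span = wave_span,
        min_age = min_age, ci_level = ci_level,
        fatal_fraction = fatal_fraction, silent_fraction = silent_fraction,
        zero_substitution = zero_substitution,
        trend_reference_year = trend_reference_year,
        n_waves = length(prevalence)
      )
    ),
    class = "pi_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Produces `stratum_estimates.csv`, `standardized.csv` and a human-readable
#' `summary.txt` in `dir`. Output is deterministic for identical inputs (no
#' timestamps).
#'
#' @param report A `pi_report` from [run_estimate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pi_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  se <- report$stratum_estimates
  for (col in c("interval_start", "interval_end")) {
    if (col %in% names(se)) se[[col]] <- as.character(se[[col]])
  }
  write_stratum_table(se, file.path(dir, "stratum_estimates.csv"))
  utils::write.csv(report$standardized, file.path(dir, "standardized.csv"),
                   row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(dir)
}

#' @export
print.pi_report <- function(x, ...) {
  cat("Prevalence-to-incidence report\n")
  cat(sprintf("  waves: %d (%s), wave span %d yr\n",
              x$config$n_waves,
              paste(x$config$wave_start_years, collapse = ", "),
              x$config$wave_span))
  if (!is.null(x$config$min_age)) {
    cat(sprintf("  standardization restricted to ages %s+\n",
                x$config$min_age))
  }
  cat("\nStandardized incidence per 100,000 person-years:\n")
  print(x$standardized, row.names = FALSE)
  if (!is.null(x$trend)) {
    cat("\n")
    print(x$trend)
    if (!is.null(x$adjusted_trend)) {
      cat("Hospitalized series: ")
      print(x$adjusted_trend)
      cat(sprintf("  annual decline %.1f%%; 10-year reduction %.0f%%\n",
                  annual_percent_decline(x$adjusted_trend),
                  percent_reduction(x$adjusted_trend, 10)))
    }
  }
  neg <- sum(x$standardized$n_negative)
  if (neg > 0) {
    cat(sprintf("\nNote: %d stratum-interval estimate(s) were negative and ",
                neg), "entered standardization unclipped.\n", sep = "")
  }
  invisible(x)
}
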