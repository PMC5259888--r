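# CSV readers/writers for the stratified table schemas, plus YAML scenario
# and run-configuration parsing. All file proportions live on [0, 1]; the
# per-100,000 scale is confined to reporting. Age bands are half-open
# [age_lo, age_hi); an empty age_hi cell denotes the open-ended top band.

read_stratum_csv <- function(path, name) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  need <- c("sex", "age_lo", "age_hi")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s '%s' is missing column(s): %s", name, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

parse_numeric_col <- function(df, col, path, allow_empty = FALSE,
                              empty_value = NA_real_) {
  raw <- df[[col]]
  empty <- is.na(raw) | raw == ""
  out <- suppressWarnings(as.numeric(raw))
  bad <- !empty & is.na(out)
  if (any(bad)) {
    stop(sprintf("non-numeric value in column '%s' of '%s' at row %d ('%s')",
                 col, path, which(bad)[1] + 1L, raw[which(bad)[1]]),
         call. = FALSE)
  }
  if (any(empty)) {
    if (!allow_empty) {
      stop(sprintf("missing value in column '%s' of '%s' at row %d",
                   col, path, which(empty)[1] + 1L), call. = FALSE)
    }
    out[empty] <- empty_value
  }
  out
}

check_proportion_col <- function(x, col, path) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop(sprintf("column '%s' of '%s' outside [0, 1] at row %d (value %s)",
                 col, path, which(bad)[1] + 1L, x[which(bad)[1]]),
         call. = FALSE)
  }
  x
}

#' Read a stratified prevalence table
#'
#' CSV schema: one row per stratum with columns `sex`, `age_lo`, `age_hi`,
#' `p` and optionally `n` (respondent count, needed for Poisson CIs) and
#' `wave_start_year` (constant; attached as an attribute). An empty `age_hi`
#' denotes the open-ended top band. Rows are validated (ranges, band overlap)
#' with row-numbered errors and returned sorted by sex then age.
#'
#' @param path Path to a CSV file.
#' @return Prevalence data.frame, possibly with a `wave_start_year`
#'   attribute.
#' @export
read_prevalence_table <- function(path) {
  df <- read_stratum_csv(path, "prevalence table")
  if (!"p" %in% names(df)) {
    stop(sprintf("prevalence table '%s' is missing column 'p'", path),
         call. = FALSE)
  }
  out <- data.frame(
    sex = df$sex,
    age_lo = parse_numeric_col(df, "age_lo", path),
    age_hi = parse_numeric_col(df, "age_hi", path, allow_empty = TRUE,
                               empty_value = Inf),
    p = check_proportion_col(parse_numeric_col(df, "p", path), "p", path)
  )
  if ("n" %in% names(df)) {
    out$n <- parse_numeric_col(df, "n", path, allow_empty = TRUE)
    if (any(!is.na(out$n) & out$n <= 0)) {
      stop(sprintf("column 'n' of '%s' must be positive", path),
           call. = FALSE)
    }
  }
  check_stratum_frame(out, path)
  out <- order_strata(out)
  rownames(out) <- NULL
  if ("wave_start_year" %in% names(df)) {
    yr <- unique(parse_numeric_col(df, "wave_start_year", path))
    if (length(yr) != 1) {
      stop(sprintf("'%s': wave_start_year must be constant within a table",
                   path), call. = FALSE)
    }
    attr(out, "wave_start_year") <- yr
  }
  out
}

#' Write a stratified table to CSV
#'
#' Inverse of the readers: numbers are written with 15 significant digits so
#' a write/read round trip is lossless well beyond 12 digits; an infinite
#' `age_hi` becomes an empty cell. A `wave_start_year` attribute on a
#' prevalence table is written as a constant column.
#'
#' @param x Stratified data.frame (prevalence, survival, mortality or
#'   standard-population schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stratum_table <- function(x, path) {
  out <- as.data.frame(x)
  if (!is.null(attr(x, "wave_start_year"))) {
    out$wave_start_year <- attr(x, "wave_start_year")
  }
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- out[[col]]
      s <- vapply(v, function(z) {
        if (is.na(z)) "" else if (is.infinite(z)) "" else
          format(z, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      if (col != "age_hi") s[is.na(v)] <- ""
      out[[col]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stratified survival table
#'
#' CSV schema: `sex`, `age_lo`, `age_hi`, `SP`, `SN`, `T` (interval years,
#' constant across rows).
#'
#' @param path Path to a CSV file.
#' @return Survival data.frame sorted by sex then age.
#' @export
read_survival_table <- function(path) {
  df <- read_stratum_csv(path, "survival table")
  miss <- setdiff(c("SP", "SN", "T"), names(df))
  if (length(miss) > 0) {
    stop(sprintf("survival table '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    sex = df$sex,
    age_lo = parse_numeric_col(df, "age_lo", path),
    age_hi = parse_numeric_col(df, "age_hi", path, allow_empty = TRUE,
                               empty_value = Inf),
    SP = check_proportion_col(parse_numeric_col(df, "SP", path), "SP", path),
    SN = check_proportion_col(parse_numeric_col(df, "SN", path), "SN", path),
    T = parse_numeric_col(df, "T", path)
  )
  if (any(out$T <= 0)) {
    stop(sprintf("column 'T' of '%s' must be positive", path), call. = FALSE)
  }
  check_stratum_frame(out, path)
  out <- order_strata(out)
  rownames(out) <- NULL
  out
}

#' Read a stratified mortality-input table
#'
#' CSV schema: `sex`, `age_lo`, `age_hi`, `M_MIin`, `M_MIout`,
#' `MV_all_cause`, `MV_disease`, optionally `M_AG` and `M_HF` for the
#' heart-disease composite. Rows with an empty `age_lo` are sex-level rows
#' to be broadcast with [expand_sex_rows()]. Vital-statistics columns must
#' already be cumulative proportions over the analysis interval.
#'
#' @param path Path to a CSV file.
#' @return Mortality data.frame (unsorted if sex-level rows are present).
#' @export
read_mortality_table <- function(path) {
  df <- read_stratum_csv(path, "mortality table")
  need <- c("M_MIin", "M_MIout", "MV_all_cause", "MV_disease")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("mortality table '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    sex = df$sex,
    age_lo = parse_numeric_col(df, "age_lo", path, allow_empty = TRUE),
    age_hi = parse_numeric_col(df, "age_hi", path, allow_empty = TRUE,
                               empty_value = Inf)
  )
  out$age_hi[is.na(out$age_lo)] <- NA_real_
  for (col in intersect(c(need, "M_AG", "M_HF"), names(df))) {
    out[[col]] <- check_proportion_col(parse_numeric_col(df, col, path),
                                       col, path)
  }
  full <- !is.na(out$age_lo)
  if (any(full)) check_stratum_frame(out[full, , drop = FALSE], path)
  out
}

#' Read a standard population
#'
#' CSV schema: `sex`, `age_lo`, `age_hi`, `count` (persons; any consistent
#' unit). An optional `label` attribute can be set by the caller.
#'
#' @param path Path to a CSV file.
#' @return Standard-population data.frame sorted by sex then age.
#' @export
read_standard_population <- function(path) {
  df <- read_stratum_csv(path, "standard population")
  if (!"count" %in% names(df)) {
    stop(sprintf("standard population '%s' is missing column 'count'", path),
         call. = FALSE)
  }
  out <- data.frame(
    sex = df$sex,
    age_lo = parse_numeric_col(df, "age_lo", path),
    age_hi = parse_numeric_col(df, "age_hi", path, allow_empty = TRUE,
                               empty_value = Inf),
    count = parse_numeric_col(df, "count", path)
  )
  if (any(out$count < 0)) {
    stop(sprintf("column 'count' of '%s' must be non-negative", path),
         call. = FALSE)
  }
  if (sum(out$count) <= 0) {
    stop(sprintf("standard population '%s' has zero total count", path),
         call. = FALSE)
  }
  check_stratum_frame(out, path)
  out <- order_strata(out)
  rownames(out) <- NULL
  out
}

#' Read a simulation scenario from YAML
#'
#' Top-level keys mirror [sim_scenario()]: `T_years`, `n_waves`, `mode`,
#' `n_per_stratum`, `seed`, `m_substeps`, `start_year`, and `strata`, a list
#' of records with `sex`, `age_lo`, `age_hi` (null/absent for the open top
#' band), `hazard`, `p_init`, `SP`, `SN`.
#'
#' @param path Path to a YAML file.
#' @return A `sim_scenario` object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$strata)) {
    stop(sprintf("scenario '%s' has no 'strata' list", path), call. = FALSE)
  }
  strata <- do.call(rbind, lapply(y$strata, function(s) {
    data.frame(
      sex = s$sex, age_lo = s$age_lo,
      age_hi = if (is.null(s$age_hi)) Inf else s$age_hi,
      hazard = s$hazard, p_init = s$p_init, SP = s$SP, SN = s$SN
    )
  }))
  args <- list(strata = strata)
  for (k in c("T_years", "n_waves", "mode", "n_per_stratum", "seed",
              "m_substeps", "start_year")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(sim_scenario, args)
}

#' Write simulated surveys as prevalence CSV files
#'
#' One file per wave, named `wave_<year>.csv`, in the same schema
#' [read_prevalence_table()] reads (including the `wave_start_year` column),
#' so simulator output pipes straight back into the estimator.
#'
#' @param waves List of prevalence tables from [generate_surveys()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_surveys <- function(waves, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(waves, function(w) {
    file.path(dir, sprintf("wave_%d.csv", attr(w, "wave_start_year")))
  }, character(1))
  for (i in seq_along(waves)) write_stratum_table(waves[[i]], paths[i])
  invisible(paths)
}
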