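# Internal validation helpers shared across modules. All stratified tables use
# the same key: sex (label), age_lo (inclusive), age_hi (exclusive; Inf for the
# open-ended top band).

check_proportion <- function(x, name) {
  if (anyNA(x)) {
    stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  }
  bad <- x < 0 | x > 1
  if (any(bad)) {
    stop(sprintf("'%s' must lie in [0, 1]; offending value(s): %s",
                 name, paste(signif(x[bad], 6), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

stratum_key <- function(df) {
  hi <- ifelse(is.finite(df$age_hi), format(df$age_hi, trim = TRUE), "Inf")
  paste(df$sex, format(df$age_lo, trim = TRUE), hi, sep = "|")
}

format_strata <- function(df) {
  hi <- ifelse(is.finite(df$age_hi), format(df$age_hi, trim = TRUE), "Inf")
  paste0(df$sex, " [", format(df$age_lo, trim = TRUE), ", ", hi, ")")
}

order_strata <- function(df) {
  df[order(df$sex, df$age_lo), , drop = FALSE]
}

# Structural checks on any stratified table: key columns present and numeric,
# age bands valid and non-overlapping within each sex.
check_stratum_frame <- function(df, name) {
  need <- c("sex", "age_lo", "age_hi")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("'%s' is missing column(s): %s", name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$age_lo) || !is.numeric(df$age_lo) || !is.numeric(df$age_hi)) {
    stop(sprintf("'%s': age_lo/age_hi must be numeric and age_lo non-missing",
                 name), call. = FALSE)
  }
  if (any(df$age_lo >= df$age_hi)) {
    i <- which(df$age_lo >= df$age_hi)[1]
    stop(sprintf("'%s': age_lo must be < age_hi (violated by %s)",
                 name, format_strata(df[i, , drop = FALSE])), call. = FALSE)
  }
  for (s in unique(df$sex)) {
    sub <- df[df$sex == s, , drop = FALSE]
    sub <- sub[order(sub$age_lo), , drop = FALSE]
    if (anyDuplicated(sub$age_lo)) {
      stop(sprintf("'%s': duplicated age band for sex '%s'", name, s),
           call. = FALSE)
    }
    if (nrow(sub) > 1) {
      ov <- sub$age_lo[-1] < sub$age_hi[-nrow(sub)]
      if (any(ov)) {
        i <- which(ov)[1]
        stop(sprintf("'%s': overlapping age bands for sex '%s': %s and %s",
                     name, s,
                     format_strata(sub[i, , drop = FALSE]),
                     format_strata(sub[i + 1, , drop = FALSE])),
             call. = FALSE)
      }
    }
  }
  invisible(df)
}

# Require table b to contain every stratum of table a; keyed error otherwise.
check_strata_align <- function(a, b, name_a, name_b) {
  miss <- setdiff(stratum_key(a), stratum_key(b))
  if (length(miss) > 0) {
    stop(sprintf("strata present in '%s' but missing from '%s': %s",
                 name_a, name_b, paste(miss, collapse = "; ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
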