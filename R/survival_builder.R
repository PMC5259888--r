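#' Combined two-year mortality after myocardial infarction
#'
#' Composes in-hospital case fatality with post-discharge mortality:
#' \deqn{M_{MI} = M_{MIin} + (1 - M_{MIin})\,M_{MIout},}
#' i.e. the complement of surviving both phases,
#' `1 - M_MI = (1 - M_MIin)(1 - M_MIout)`.
#'
#' @param M_MIin In-hospital MI mortality proportion.
#' @param M_MIout Two-year post-discharge MI mortality proportion.
#' @return Combined two-year mortality proportion(s).
#' @examples
#' mi_two_year_mortality(0.1, 0.1)  # 0.19
#' @export
mi_two_year_mortality <- function(M_MIin, M_MIout) {
  check_proportion(M_MIin, "M_MIin")
  check_proportion(M_MIout, "M_MIout")
  M_MIin + (1 - M_MIin) * M_MIout
}

#' Project mortality forward with a constant annual decline
#'
#' Applies a multiplicative secular improvement to a baseline mortality
#' proportion: `M_base * (1 - annual_decline)^(target_year - baseline_year)`.
#' The default 3%/yr decline reflects the published secular improvement in MI
#' case survival. Back-extrapolation (target before baseline) is refused.
#'
#' @param M_base Baseline mortality proportion.
#' @param baseline_year Calendar year the baseline refers to.
#' @param target_year Calendar year to project to (>= baseline_year).
#' @param annual_decline Annual proportional decline in \[0, 1).
#' @return Projected mortality proportion(s).
#' @examples
#' decline_mortality(0.2, 1999, 2009)  # 0.2 * 0.97^10
#' @export
decline_mortality <- function(M_base, baseline_year, target_year,
                              annual_decline = 0.03) {
  check_proportion(M_base, "M_base")
  if (annual_decline < 0 || annual_decline >= 1) {
    stop("'annual_decline' must lie in [0, 1)", call. = FALSE)
  }
  if (any(target_year < baseline_year)) {
    stop("'target_year' precedes 'baseline_year'; no back-extrapolation",
         call. = FALSE)
  }
  M_base * (1 - annual_decline)^(target_year - baseline_year)
}

#' Two-year survival fraction for MI patients
#'
#' The complement of the combined two-year mortality, `SP_MI = 1 - M_MI`.
#'
#' @param M_MI Combined two-year MI mortality proportion
#'   (see [mi_two_year_mortality()]).
#' @return Survival proportion(s).
#' @export
sp_mi <- function(M_MI) {
  check_proportion(M_MI, "M_MI")
  1 - M_MI
}

#' Two-year survival fraction for prevalent heart disease
#'
#' Heart disease here is the composite of MI, angina and heart failure; its
#' survival fraction is one minus the component-weighted mortality mixture:
#' \deqn{SP_{HD} = 1 - M_{MI} w_{MI} - M_{AG} w_{AG} - M_{HF} w_{HF},}
#' with weights the prevalence shares of the three components (summing to 1).
#'
#' @param M_MI,M_AG,M_HF Two-year mortality proportions of MI, angina and
#'   heart failure.
#' @param weights Numeric length-3 vector of component weights
#'   (MI, angina, heart failure), summing to 1 within 1e-9.
#' @return Survival proportion(s).
#' @examples
#' sp_heart_disease(0.19, 0.10, 0.40, weights = c(0.5, 0.3, 0.2))  # 0.795
#' @export
sp_heart_disease <- function(M_MI, M_AG, M_HF, weights) {
  check_proportion(M_MI, "M_MI")
  check_proportion(M_AG, "M_AG")
  check_proportion(M_HF, "M_HF")
  if (length(weights) != 3 || anyNA(weights) || any(weights < 0)) {
    stop("'weights' must be 3 non-negative values (MI, angina, heart failure)",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("component weights must sum to 1 (got %.12f)", sum(weights)),
         call. = FALSE)
  }
  1 - M_MI * weights[1] - M_AG * weights[2] - M_HF * weights[3]
}

#' Disease-negative survival fraction from vital statistics
#'
#' Survival of the disease-free population over the interval, taken as the
#' complement of all-cause mortality net of disease-attributed mortality:
#' `SN = 1 - (MV_all_cause - MV_disease)`. Both inputs must already be
#' expressed as cumulative mortality proportions over the same interval.
#' Disease mortality exceeding all-cause mortality is a data inconsistency
#' and raises an error rather than being clamped.
#'
#' @param MV_all_cause All-cause cumulative mortality proportion over the
#'   interval.
#' @param MV_disease Disease-attributed cumulative mortality proportion over
#'   the same interval.
#' @return Survival proportion(s).
#' @examples
#' sn_from_vitals(0.05, 0.01)  # 0.96
#' @export
sn_from_vitals <- function(MV_all_cause, MV_disease) {
  check_proportion(MV_all_cause, "MV_all_cause")
  check_proportion(MV_disease, "MV_disease")
  if (any(MV_disease > MV_all_cause)) {
    stop("'MV_disease' exceeds 'MV_all_cause'; inconsistent vital statistics",
         call. = FALSE)
  }
  1 - (MV_all_cause - MV_disease)
}

#' Broadcast sex-level mortality rows across age bands
#'
#' Mortality sources often report case fatality by sex only. Rows of `tbl`
#' with missing `age_lo`/`age_hi` are expanded to every age band of the same
#' sex appearing in `strata`; fully stratified rows pass through unchanged.
#'
#' @param tbl Data.frame with columns `sex`, `age_lo`, `age_hi` plus value
#'   columns; `age_lo = NA` marks a sex-level row.
#' @param strata Data.frame carrying the target stratum set (columns `sex`,
#'   `age_lo`, `age_hi`).
#' @return Data.frame on the full stratum set of `strata`.
#' @export
expand_sex_rows <- function(tbl, strata) {
  check_stratum_frame(strata, "strata")
  sexwise <- is.na(tbl$age_lo)
  keep <- tbl[!sexwise, , drop = FALSE]
  if (any(sexwise)) {
    pieces <- lapply(which(sexwise), function(i) {
      bands <- strata[strata$sex == tbl$sex[i], c("age_lo", "age_hi"),
                      drop = FALSE]
      if (nrow(bands) == 0) {
        stop(sprintf("no target age bands for sex '%s'", tbl$sex[i]),
             call. = FALSE)
      }
      row <- tbl[rep(i, nrow(bands)), , drop = FALSE]
      row$age_lo <- bands$age_lo
      row$age_hi <- bands$age_hi
      row
    })
    keep <- rbind(keep, do.call(rbind, pieces))
  }
  out <- order_strata(keep)
  rownames(out) <- NULL
  out
}

#' Build a per-stratum survival table from mortality inputs
#'
#' Assembles the `SP`/`SN` survival pairs consumed by [estimate_wave_pair()]
#' from a stratified mortality table. The disease-positive side is either
#' the MI survival `1 - M_MI` (default), with `M_MI` composed from in-hospital
#' and post-discharge mortality and projected to `target_year` by the annual
#' decline, or the component-weighted heart-disease survival when `weights`
#' is supplied (requires `M_AG` and `M_HF` columns). The disease-negative
#' side comes from vital statistics via [sn_from_vitals()].
#'
#' @param mortality Data.frame with columns `sex`, `age_lo`, `age_hi`,
#'   `M_MIin`, `M_MIout`, `MV_all_cause`, `MV_disease`, and (for the
#'   heart-disease composite) `M_AG`, `M_HF`. Vital-statistics columns must
#'   already be cumulative proportions over the interval `T_years`.
#' @param baseline_year Calendar year the mortality inputs refer to.
#' @param target_year Calendar year of the first survey of the wave pair the
#'   table will serve; defaults to `baseline_year` (no projection).
#' @param annual_decline Annual proportional decline in MI mortality
#'   (default 0.03); applied to the combined two-year mortality.
#' @param weights Optional length-3 component weights (MI, angina, heart
#'   failure) switching on the heart-disease composite.
#' @param T_years Interval length in years carried into the output.
#' @return Data.frame with columns `sex`, `age_lo`, `age_hi`, `SP`, `SN`, `T`.
#' @export
build_survival_table <- function(mortality, baseline_year,
                                 target_year = baseline_year,
                                 annual_decline = 0.03, weights = NULL,
                                 T_years = 2) {
  check_stratum_frame(mortality, "mortality")
  need <- c("M_MIin", "M_MIout", "MV_all_cause", "MV_disease")
  miss <- setdiff(need, names(mortality))
  if (length(miss) > 0) {
    stop(sprintf("mortality table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  M_MI <- mi_two_year_mortality(mortality$M_MIin, mortality$M_MIout)
  M_MI <- decline_mortality(M_MI, baseline_year, target_year, annual_decline)
  if (is.null(weights)) {
    SP <- sp_mi(M_MI)
  } else {
    if (!all(c("M_AG", "M_HF") %in% names(mortality))) {
      stop("heart-disease weights supplied but 'M_AG'/'M_HF' columns missing",
           call. = FALSE)
    }
    SP <- sp_heart_disease(M_MI, mortality$M_AG, mortality$M_HF, weights)
  }
  SN <- sn_from_vitals(mortality$MV_all_cause, mortality$MV_disease)
  out <- data.frame(
    sex = mortality$sex, age_lo = mortality$age_lo, age_hi = mortality$age_hi,
    SP = SP, SN = SN, T = T_years
  )
  out <- order_strata(out)
  rownames(out) <- NULL
  out
}
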