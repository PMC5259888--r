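Package: previnc
Title: Prevalence-to-Incidence Estimation for Irreversible Chronic Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates age- and sex-standardized incidence of irreversible
    chronic disease (exemplified by myocardial infarction and heart disease)
    from two or more cross-sectional prevalence surveys, using a modified
    Hallett prevalence-to-incidence model. Provides closed-form per-stratum
    incidence estimation with exact Poisson confidence intervals, construction
    of two-year survival fractions from case fatality and vital statistics,
    direct standardization to a census population with a zero-prevalence
    substitution rule, conversion of all-event to hospitalized-event incidence,
    linear trend extraction, and a synthetic open-population simulator for
    validating the estimator against known incidence hazards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    jsonlite
Config/testthat/edition: 3
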