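Package: ccmeta
Title: Individualized Cervical Cancer Risk from Pooled Case-Control Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A meta-model that synthesizes odds-ratio evidence from
    heterogeneous case-control studies of cervical cancer risk factors in
    Chinese women into an individualized absolute risk prediction with
    uncertainty. Implements standard-error imputation for log odds ratios
    (from confidence intervals, p-values via the Altman-Bland conversion, or
    chi-square statistics with marginal totals via contingency-table
    reconstruction), per-study baseline calibration against a population
    incidence, Monte Carlo propagation of odds-ratio and prevalence
    uncertainty, DerSimonian-Laird random-effects pooling of per-study
    log-risks, inverse-variance pooled odds-ratio rankings, leave-one-out
    sensitivity analysis, and generators for synthetic study tables and
    dependency-aware patient profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
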