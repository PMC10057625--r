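Package: ppglucose
Title: Blood Glucose Estimation from In-Ear Photoplethysmography
Version: 0.1.0
Authors@R:
    person("PPG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating blood glucose levels (BGL)
    from single-channel photoplethysmography (PPG) recordings: zero-phase
    Butterworth pre-processing (DC/AC separation, upsampling, lower-envelope
    baseline removal, peak and trough detection), template matched-filter
    cycle quality control, extraction of 18 morphological and Teager-Kaiser
    energy features per cardiac cycle, high/low-glucose ensemble-cycle
    statistics, subject-specific bagged and least-squares-boosted
    regression-tree models with day-wise train/test splits and grouped
    cross-validation, and clinical evaluation via the Clarke error grid,
    MARD, RMSE and ISO 15197 tolerance rates. Includes a synthetic cohort
    generator emulating glucose-modulated PPG morphology across four
    diabetic phenotypes for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
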