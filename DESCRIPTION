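Package: popbenefit
Title: Population-Level Risk-Benefit Indices for Biomarkers in Disease
    Detection and Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the population-level trade-off between benefit and
    harm when a binary or continuous biomarker (or risk factor) is used to
    trigger early-detection or preventive intervention. Reconstructs the
    population 2x2 exposure-by-disease table from an odds ratio and
    marginal prevalences, computes sensitivity, specificity and the
    population attributable risk percent (PAR%), and evaluates the 'naive'
    ratio of population benefit (RPB) together with decision-curve net
    benefit and absolute-gain quantities, with utility-loss weights for
    false positives, prevention efficacy and adverse-effect parameters,
    and stratified confounder adjustment. Continuous markers are modelled
    with equal-variance Gaussian class-conditional densities calibrated to
    a per-unit odds ratio, with threshold policies (fixed sensitivity,
    fixed specificity, balanced) and ROC curves. Includes a synthetic
    cohort simulator with plug-in empirical estimators and a command-line
    interface that regenerates the reference numerical tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
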