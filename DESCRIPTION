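Package: qeegmeta
Title: Quantitative EEG Features and Subgroup Meta-Analysis for Multicenter Delirium Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-running a multicenter quantitative EEG (qEEG)
    delirium analysis end to end. Simulates multichannel epoched EEG cohorts
    with known ground-truth spectral slowing and phase-coupling structure,
    applies the study's preprocessing contract (channel exclusion, epoch
    selection, average reference), computes relative band power, peak
    frequency and the phase lag index (PLI), and pools delirious versus
    non-delirious standardized mean differences (Hedges' g) across
    etiology-by-site subgroups with a restricted maximum likelihood (REML)
    random-effects model, Cochran's Q and the I-squared heterogeneity
    statistic. Includes bootstrap descriptive confidence intervals,
    status-stratified heterogeneity, age-adjusted regression, leave-site-out
    sensitivity analysis, and a minimal EDF reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
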