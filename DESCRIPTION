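Package: cortasym
Title: Stage-Stratified Cortical Atrophy-Rate and Hemispheric Asymmetry
    Analysis for Parkinson's Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-sectional analysis of regional cortical thickness in
    Parkinson's disease cohorts stratified by disease duration. Estimates
    per-region atrophy rates (mm/year) by stage with bootstrap percentile
    confidence intervals, tests Early-minus-Late slope differences with a
    confidence-interval sign rule, compares group mean thickness per region
    with Welch t-tests under per-hemisphere Benjamini-Hochberg false
    discovery rate control, and provides handedness and motor-laterality
    sub-analyses (duration-thickness correlations, paired hemispheric
    comparisons). Includes a seeded synthetic-cohort generator that emulates
    the clinical table and FreeSurfer aparcstats2table regional thickness
    layout (Destrieux parcellation) for parameter-recovery and calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
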