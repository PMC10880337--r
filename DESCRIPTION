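Package: leddscreen
Title: Claims-Based Drug-Repurposing Screen Using Levodopa-Equivalent Daily Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for screening marketed drugs (antihistamines in
    the shipped configuration) for association with slower Parkinson's disease
    progression in prescription-claims data. Builds continuous drug-exposure
    episodes from dispensing records, assigns index dates by the exposed
    group's median diagnosis-to-first-prescription interval, converts PD
    medication to levodopa-equivalent daily dose (LEDD) averaged over 90-day
    windows flanking the index date, performs 1:3 propensity-score
    nearest-neighbour caliper matching, and compares per-patient LEDD
    increment ratios between exposed and matched unexposed patients with an
    unpaired t-test. Includes a synthetic claims generator with confounded
    exposure and progressing dose trajectories so every stage is testable
    without access to a real claims registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
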