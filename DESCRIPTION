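Package: mmpibn
Title: Dual Gaussian Bayesian Networks for MMPI-2 Clinical-Scale Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns separate linear-Gaussian Bayesian networks for two
    diagnostic groups (healthy adults and patients with schizophrenia) from
    MMPI-2 clinical-scale T-score profiles, classifies new profiles by the
    log likelihood ratio of the two fitted networks, contrasts the groups'
    Pearson correlation structure with a permutation test, and runs what-if
    conditional imputation among the Depression (D), Psychasthenia (Pt) and
    Schizophrenia (Sc) scales. Includes hybrid constraint/score structure
    learning (Fisher-z partial-correlation skeleton discovery followed by
    BIC hill climbing), propensity-score matching of cohorts on
    demographics, and a calibrated synthetic two-group cohort generator so
    every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
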