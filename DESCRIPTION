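Package: prsrisk
Title: Polygenic Risk Score Stratification and Absolute Risk of Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for polygenic risk score (PRS) based risk stratification of
    breast cancer in population cohorts: genotype quality control, allele
    harmonization against published PRS weight sets, additive PRS scoring and
    cohort standardization, discrimination metrics (ROC AUC, odds ratio per
    standard deviation), a left-truncated right-censored Cox proportional
    hazards fit of age at onset on the standardized PRS with Harrell's
    concordance index, and an absolute-risk engine that calibrates the
    baseline hazard to registry marginal incidence under susceptible depletion
    and integrates age-specific risk against competing mortality to produce
    lifetime and 10-year risk curves by PRS percentile. Includes synthetic
    cohort, genotype, weight-set and rate-table generators with known ground
    truth so every stage is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
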