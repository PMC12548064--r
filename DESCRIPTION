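Package: methylong
Title: Longitudinal Candidate-CpG Methylation Association Analysis for
    ART Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for longitudinal candidate-region DNA
    methylation analysis comparing children conceived by assisted
    reproductive technology (ART) with naturally conceived children.
    Implements beta/M-value transforms, twin deduplication, median +/-
    k*MAD outlier filtering, per-CpG linear mixed models with a 96-well
    plate random intercept and Wald inference, Benjamini-Hochberg FDR
    correction within the candidate probe family, a within-child change
    statistic built from standardized timepoint residuals, and a
    Monte-Carlo power/sample-size simulation with heavy-tailed (Student t)
    M-value noise. Ships a synthetic two-timepoint cohort generator that
    emulates the covariate structure of a birth-cohort methylation study
    so the full pipeline is testable without access-restricted data, plus
    a bundled 25-probe BRCA1/NBR2 promoter manifest (hg19).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
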