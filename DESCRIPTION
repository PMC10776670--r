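Package: exprsurv
Title: Expression-Cutoff Survival Stratification for Biomarker Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking a continuous biomarker (e.g. qRT-PCR relative
    mRNA expression) to clinical outcome in right-censored cohorts. The
    centrepiece is an exhaustive optimal-cutpoint scan restricted to the
    interquartile range of expression: every observed cutoff is evaluated with
    a single-covariate Cox proportional-hazards fit, p-values are adjusted
    across the scan by the Benjamini-Hochberg step-up procedure, and the
    minimum-FDR cutoff is selected with highest-hazard-ratio tie-breaking.
    Supporting machinery includes Kaplan-Meier estimation, the log-rank test,
    delta-Ct relative expression quantification, rank-based and t group
    comparisons, exponential growth-kinetics doubling times, four-parameter
    logistic IC50 fitting, and a synthetic-cohort generator with known ground
    truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
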