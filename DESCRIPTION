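Package: mrflow
Title: Two-Sample Mendelian Randomization with Instrument Selection,
    Sensitivity Diagnostics and Batch Evidence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end two-sample Mendelian randomization from GWAS
    summary statistics: instrument selection (p-value thresholding, LD
    clumping against an injectable r-squared lookup, variance-explained
    and F-statistic weak-instrument filtering, Steiger directionality),
    allele harmonization with palindromic-variant resolution by allele
    frequency, five causal-effect estimators (inverse-variance weighted,
    MR-Egger, weighted median, simple and weighted mode) plus the
    single-instrument Wald ratio, a sensitivity battery (Cochran's Q,
    Egger intercept, recursive MR-PRESSO outlier removal, leave-one-out),
    a primary-method decision rule with per-taxonomic-level Bonferroni
    evidence classification, and a seeded synthetic two-sample GWAS
    generator with known ground truth for calibration and recovery
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
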