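Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: reading and allele harmonization of summary tables, LD
    clumping and instrument-strength assessment, causal estimators (Wald
    ratio, fixed and multiplicative random-effects inverse-variance
    weighting, MR-Egger regression, weighted median, multivariable IVW),
    heterogeneity and pleiotropy diagnostics (Cochran's Q, Egger intercept,
    MR-PRESSO global, outlier and distortion tests, leave-one-out), and a
    summary-statistics simulator with configurable pleiotropy for
    calibration and power studies, plus an end-to-end analysis pipeline
    with report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
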