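Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics: instrument selection (genome-wide
    significance filtering, greedy LD clumping, confounder-trait screening),
    allele harmonization with palindromic-SNP handling, five causal-effect
    estimators (inverse-variance weighted, MR-Egger, weighted median, simple
    and weighted mode), instrument-strength metrics (per-SNP and total R2, F
    statistic), and sensitivity analyses (Cochran Q and I2 heterogeneity,
    Egger-intercept pleiotropy test, leave-one-out, MR-PRESSO global, outlier
    and distortion tests). Includes a synthetic summary-statistics generator
    with known ground truth for validating the full pipeline, and an
    orchestrated bidirectional analysis mirroring a published IBD-rosacea
    case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
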