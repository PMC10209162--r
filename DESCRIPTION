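Package: SummaryMR
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization on GWAS summary
    statistics: parsing and quality control of association tables, greedy LD
    clumping with F-statistic screening of instruments, allele harmonization,
    four causal-effect estimators (inverse-variance weighted, MR-Egger,
    weighted median, robust adjusted profile score), Cochran heterogeneity and
    leave-one-out diagnostics, MR-PRESSO global and outlier tests with
    outlier trimming, Benjamini-Hochberg correction across outcomes, and a
    synthetic summary-statistics generator with known ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
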