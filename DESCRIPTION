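Package: metamr
Title: Two-Sample Mendelian Randomization for Metabolome-Wide Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-sample Mendelian randomization from GWAS summary
    statistics, oriented towards metabolome-wide screens against a single
    outcome. Covers instrument selection (p-value thresholding, greedy LD
    clumping on a user-supplied pairwise r-squared table, R-squared and
    F-statistic strength filters), allele harmonization with palindromic-SNP
    policies, four causal-effect estimators (Wald ratio, fixed-effect
    inverse-variance weighted, MR-Egger, weighted median) plus the MR-PRESSO
    global, outlier and distortion tests, Cochran Q and I-squared
    heterogeneity diagnostics, Bonferroni significance tiering with a
    sensitivity-based robustness gate, replication against alternative
    outcome GWAS, and hypergeometric over-representation analysis of
    candidate metabolites against GMT pathway libraries. A synthetic
    summary-statistics generator with known causal effect, pleiotropy and
    outlier structure supports parameter-recovery testing, and a transcribed
    25-SNP instrument table for the metabolite 5-oxoproline against
    intelligence ships as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
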