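Package: hrdbench
Title: Benchmarking and Threshold Calibration for Homologous Recombination
    Deficiency Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking continuous homologous recombination
    deficiency (HRD) classifier scores (such as CHORD and HRDetect) against
    gene-level evidence of biallelic inactivation in HR-related genes.
    Labels tumors as truly HR-deficient from germline, somatic, loss of
    heterozygosity, promoter methylation and deep deletion events; evaluates
    classifiers with ROC and precision-recall analysis, stratified bootstrap
    AUC confidence intervals and the paired DeLong test; calibrates
    cancer-type-specific decision thresholds by tenfold nested
    cross-validation; and quantifies explained versus unexplained
    HRD-classified cases with binomial proportion intervals, the partially
    overlapping samples z-test for dichotomous outcomes, and pairwise
    one-sided Fisher tests with Bonferroni correction. Includes a synthetic
    cohort generator so the whole pipeline is testable without access to
    per-sample supplementary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
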