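Package: gdfmr
Title: Two-Sample Mendelian Randomization of Circulating GDF-15 on
    Cardiovascular Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for two-sample Mendelian randomization of
    circulating growth differentiation factor 15 (GDF-15) against nine
    cardiovascular outcomes using GWAS summary statistics. Provides
    instrument selection (genome-wide significance filter, greedy LD
    pruning, pleiotropy exclusion lists), exposure/outcome allele
    harmonization, Wald-ratio, inverse-variance-weighted, weighted-median
    and MR-Egger estimators with Cochran Q heterogeneity and Egger
    intercept pleiotropy diagnostics, plain-text readers and writers for
    summary statistics and LD matrices, and a synthetic summary-statistics
    generator with known causal effect and configurable horizontal
    pleiotropy for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
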