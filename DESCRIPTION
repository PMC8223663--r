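Package: notch3risk
Title: Cysteine-Altering NOTCH3 Variants, Firth Logistic Regression and
    Small-Vessel-Disease Phenotype Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-scale analysis of cysteine-altering
    missense variants in NOTCH3, the gene mutated in CADASIL. Provides
    variant ascertainment with mapping onto the 34 EGF-like repeat (EGFR)
    domains, a from-scratch Firth bias-reduced logistic regression engine
    with penalized-likelihood profile confidence intervals and likelihood
    ratio tests, a phenotype association battery (binary and transformed
    continuous outcomes with FDR control), polygenic-score risk-equivalence
    statistics, matched case-control comparison of visual MRI ratings, a
    synthetic cohort generator emulating the assumed data structure, and an
    end-to-end pipeline with population attributable fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
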