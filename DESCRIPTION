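Package: fidelitr
Title: Transcriptomic Fidelity Scoring for Preclinical Cancer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how well preclinical cancer models (cell lines,
    patient-derived xenografts) recapitulate tumor and non-diseased tissue
    gene expression. Computes Spearman rank correlations between model
    samples and tissue cohorts over configurable gene subsets (most-variable
    genes, tumor-purity-correlated genes, tissue-specific genes), summarises
    them as per-model medians and a matched-origin rank-specificity
    statistic, compares model classes with rank-sum tests, classifies
    individual genes as correlated or anticorrelated between model and
    tissue groups, and tests gene classes for over-representation against
    GMT collections with a hypergeometric test. Ships a negative-binomial
    synthetic-cohort generator with tissue identity signals, tumor-purity
    admixture and tunable model drift, with full ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
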