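Package: metasig
Title: Gene Signatures of Melanoma Metastasis via GA/KNN Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a computational pipeline for
    discovering gene-expression signatures that distinguish primary from
    regionally metastatic melanoma. Provides a genetic-algorithm wrapper
    around a k-nearest-neighbour classifier scored by leave-one-out
    cross-validation (GA/KNN), a resampled 75/25 train/test evaluation
    harness with per-sample accuracy aggregation and gene selection-frequency
    ranking, anchor-gene Spearman co-expression tables with rank-product
    aggregation across datasets, and a combinatorial microRNA seed-site
    scanner allowing one G:U wobble pair. A synthetic-data module generates
    two-class expression matrices with planted differential and correlated
    genes, and UTR sequences with planted seed sites, so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
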