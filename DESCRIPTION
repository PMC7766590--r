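Package: cindr
Title: Signature-Reversal and Pharmacovigilance Screening for Drug
    Repositioning in Cisplatin-Induced Nephrotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico drug-repositioning toolkit built around
    cisplatin-induced nephrotoxicity. Constructs a cross-dataset gene
    expression signature from count matrices (negative-binomial
    differential expression, ortholog mapping, direction-consistent
    intersection, hypergeometric gene-set enrichment), scores reversal
    relationships against a reference perturbagen library with a
    connectivity-map-style weighted Kolmogorov-Smirnov statistic and tau
    percentiles, screens adverse-event report tables for protective
    co-medications by reporting odds ratio, and intersects the two
    candidate lists. A synthetic-data module generates all pipeline
    inputs with planted truth so every stage is testable offline.
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
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
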