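Package: heterotag
Title: Gene-Action Patterns and Trait Heterosis from DGE Tag Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of hybrid-vs-parent differential expression from
    digital gene expression (DGE) tag profiling. Builds NlaIII
    (CATG)-anchored tag references from transcript sequences, maps clean
    tags to genes by exact match, normalises counts to transcripts per
    million clean tags (TPM), classifies every gene into one of nine
    gene-action patterns (no difference, over-/under-parents, dominance
    toward either parent, additive) from F1-vs-parent log2 fold
    differences, extracts genes with consistent trends between a cross and
    its reciprocal cross, and correlates per-group pattern proportions
    with trait heterosis rates. Includes a fully seeded synthetic-data
    generator that plants known gene-action classes and pattern-trait
    correlations so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
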