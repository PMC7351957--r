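Package: phylostage
Title: Cross-Species Identification of Conserved Developmental Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating evolutionarily conserved developmental stages
    from multi-species developmental transcriptomes. Whole-embryo expression
    profiles of shared ortholog groups are compared with a rank-correlation
    expression distance (1 - Spearman), every cross-species stage combination
    is scored along a rooted species tree by progressive profile averaging,
    and each stage is summarised by Ptop, the percentage of the top-1% most
    conserved stage combinations that include it. Replicate-level uncertainty
    is quantified by resampling one biological replicate per stage (BRI
    tables) and stage effects are tested with a tie-corrected Friedman test.
    Companion modules cover reciprocal-best-hit one-to-one orthology and
    supergene concatenation, Tajima's relative rate test, a lineage gene-loss
    presence screen, k-mer-histogram genome-size estimation, and seeded
    synthetic-data generators that produce every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
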