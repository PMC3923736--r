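Package: rddclone
Title: Clone-Level RNA-DNA Difference Calling and Effect Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises RNA-DNA differences (RDDs) in
    Sanger-sequenced cDNA clones by global alignment against a genomic
    coding consensus. Provides a seeded clone simulator with planted
    edits and a ground-truth manifest, affine-gap pairwise alignment
    with canonical (left-normalised) gap placement, per-clone event
    calling with an RNA-level variant nomenclature, frameshift-aware
    re-translation into five protein-effect categories, and tissue-level
    statistics: gene-by-tissue count matrices, the 12-class substitution
    spectrum, 3'-neighbour context bias, synonymous splits, per-clone
    rates and complete-linkage hierarchical clustering of tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
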