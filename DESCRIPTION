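Package: mulmir
Title: Conserved and Novel miRNA Discovery from Mulberry Small-RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style implementation of a plant small-RNA analysis
    pipeline for mulberry (Morus notabilis) tissue libraries: read cleaning and
    collapsing, annotation of reads into non-coding RNA and genomic categories,
    conserved miRNA cataloguing with cross-species conservation profiling,
    hairpin-based novel miRNA prediction under Mireap-style plus manual
    structural criteria (including MFEI and miRNA-star rescue),
    position-weighted miRNA target prediction under Allen-Schwab
    complementarity rules, reads-per-million tissue-bias calling, and 2^-ddCt
    relative quantification of stem-loop qRT-PCR data. Ships a built-in
    nearest-neighbor RNA folding engine and a seeded synthetic-data generator
    with machine-readable ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    S4Vectors,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    tibble,
    tidyr,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
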