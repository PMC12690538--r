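Package: pirnakit
Title: Phenotyping piRNA-Pathway Mutants from Small-RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for phenotyping Drosophila piRNA-pathway mutants
    from small-RNA sequencing libraries. Implements the full analysis chain:
    3' adapter trimming and randomized-end (UMI) removal, 18-40 nt size
    selection, hierarchical filtering against infrastructural RNAs,
    endogenous-siRNA (hpRNA) extraction for normalisation, exhaustive
    mismatch-tolerant mapping of piRNA candidates to transposon consensus
    sequences with best-stratum multi-hit reporting, per-transposon
    siRNA-normalised abundance and fold-change tables, the ping-pong linkage
    z-score on the 5'-5' overlap spectrum, and the +1U phasing z-score around
    piRNA 3' ends. Ships a seeded synthetic-library generator that plants
    ping-pong pairs, size classes, nucleotide biases and genotype effect
    sizes so every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringi,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
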