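Package: pirnascape
Title: Gonadal piRNA Cluster and Transposable-Element Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide analysis of
    PIWI-interacting RNAs (piRNAs) and transposable elements: selection and
    mapping of 24-32 nt small-RNA reads with a seed-constrained mismatch rule,
    multimapper weight reallocation by local unique-mapper density, ping-pong
    (10-nt 5' overlap) signature Z-scores and 1U/10A base biases, piRNA-cluster
    calling by density and assembly-style detectors, per-base genome
    classification with transposon-first priority, Kimura two-parameter
    transposon divergence landscapes with a molecular-clock age axis, and
    exon-anchored synteny of piRNA clusters between (sub)genomes.  A synthetic
    genome and small-RNA read simulator with machine-readable truth sets makes
    the whole pipeline testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
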