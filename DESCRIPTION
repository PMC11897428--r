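Package: unitigr
Title: Abundance Unitig Matrices from Multi-Sample Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-sample abundance unitig matrices from raw sequencing
    reads. Counts canonical k-mers per sample, assembles and filters a
    multi-sample k-mer abundance matrix, compacts the surviving k-mers into
    the maximal unitigs of a bidirected de Bruijn graph, and reports, for
    every unitig and sample, the fraction of the unitig's k-mers that are
    present and their average abundance. Includes a presence-absence mode,
    a deterministic synthetic-data generator for genomes, mutated sample
    variants and error-bearing reads, and a command-line interface exposing
    each pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
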