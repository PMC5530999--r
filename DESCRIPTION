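Package: markerforge
Title: Made-to-Measure Marker Selection and Bait Design for Targeted
    Sequence Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers homologous single-copy loci from two or more
    transcriptome assemblies (optionally anchored to whole-genome data),
    infers exon/intron structure by spliced transcript-to-genome mapping,
    ranks candidate markers and greedily selects an optimal set under a
    fixed hybridisation-bait budget, and post-processes captured contigs
    into per-marker alignable sequences with IUPAC-aware merging and
    variability statistics.  Ships a k-mer seeded local-alignment engine
    backed by an exact Smith-Waterman reference aligner, and a
    synthetic-data generator with a known truth table for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
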