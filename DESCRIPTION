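Package: pbletools
Title: Transposon Integration Junctions, Inverted-Repeat Annotation and
    Interval Overlap Statistics for piggyBac-Like Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for piggyBac-like element (pble) integration
    studies. Calls chromosome-donor junction breakpoints from LAM-PCR style
    junction reads, classifies each unique junction by target-site-duplication
    (TTAA) and terminal-inverted-repeat propriety, annotates pble-like
    inverted repeats, exact non-overlapping motifs and tandem-unit runs in
    genomic sequence, and assesses the significance of overlap between peak
    intervals and repeat annotations with chromosome-preserving,
    non-overlapping permutation shuffles. A synthetic-data generator produces
    genomes, donor constructs, integration events, junction reads and
    peak/annotation interval sets with known ground truth so that every stage
    of the pipeline can be exercised end to end.
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
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
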