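Package: pefusion
Title: Fusion Transcript Discovery from Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate fusion transcripts from aligned paired-end
    RNA-seq read pairs, removes library-preparation and misalignment artifacts
    through a cascade of seven filters (paralogy, small-scale sequence
    similarity, repeats, abnormal insert size on composite gene models,
    ribosomal contamination, expression consistency, PCR pile-up), scores the
    surviving candidates with supportive-pairs-per-million statistics (SPER,
    expected SPER, DASPER, RESPER, LSPER) and resolves exact breakpoint
    junction sequences with a tiled fusion-junction library. Includes a
    seeded synthetic-data generator (genome, annotation, reads, implanted
    fusions and artifact classes with per-read truth labels) so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    stringi,
    ggplot2,
    generics,
    jsonlite,
    matrixStats,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Config/testthat/edition: 3
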