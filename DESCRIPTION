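Package: tileChIP
Title: Tiling-Array ChIP-chip Peak Calling, Interval Enrichment, and
    Chromatin Profile Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for two-color tiling-array ChIP-chip
    experiments. Implements per-array neighborhood-model peak calling
    from probe-level p-values, ranked genomic-feature annotation of
    peaks, divergently-paired-gene discovery and binding rules,
    chromosome- and size-preserving permutation enrichment of interval
    overlaps with z-tests, anchor-relative sliding-window signal
    meta-profiles (TSS, domain boundary, and domain center anchored),
    RNA polymerase II pausing classification, per-gene histone-mark
    differential tests with FDR control, PWM and IUPAC-consensus motif
    scanning against Markov backgrounds with exact score-distribution
    p-values, Hodges-Lehmann pseudomedian signal smoothing for track
    export, and delta-delta-Ct qPCR quantification. Includes a
    synthetic-data generator with known ground truth (planted peaks,
    depleted domains, paused-polymerase regimes, planted motifs) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
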