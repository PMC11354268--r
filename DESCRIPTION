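Package: riboTE
Title: Translatome-Transcriptome Integration for Ribosome Profiling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for integrating ribosome profiling (Ribo-seq) with matched
    RNA-seq: footprint quality control (read-length distribution, region
    occupancy, 3-nt periodicity metagene profiles), FPKM and translational
    efficiency (TE) computation, simplified negative-binomial differential
    calling at the transcriptional and translational levels, nine-quadrant
    transcription-translation classification, TE-bin sequence-feature analysis
    (length, GC content, normalized minimum free energy), and upstream open
    reading frame (uORF) discovery and characterization with Kozak-context
    profiling. Includes a fully deterministic synthetic-data generator with
    known ground truth so every stage can be exercised and calibrated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: RiboSeq, Transcriptomics, Translation, DifferentialExpression,
    Sequencing, QualityControl
RoxygenNote: 7.3.3
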