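Package: riboscope
Title: Translation Initiation Site Calling from Ribosome Profiling Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects translated open reading frames (ORFs) from ribosome
    profiling data by scoring every transcript position for translation
    initiation with a small transformer encoder that consumes only the
    5'-end position and length of ribosome-protected fragments. Includes
    transcript-space alignment ingestion, masked self-supervised
    pretraining and chromosome-fold supervised training, greedy ORF
    construction with start-codon filtering and ATG neighborhood
    correction, non-canonical ORF taxonomy (uORF, uoORF, intORF, dORF,
    doORF, lncRNA-ORF, CDS variant), ORF-library ROC/PR benchmarking,
    TPM quantification, and a synthetic Ribo-Seq simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    rlang,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
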