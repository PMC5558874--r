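Package: clonetrack
Title: Clonal Tracking of Barcoded Leukaemia Xenografts from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lentiviral cellular-barcoding experiments in
    xenotransplanted acute lymphoblastic leukaemia. Simulates the full
    experiment (random barcode library, transduction, transplant bottleneck,
    organ-specific clonal expansion with a spleen-versus-bone-marrow niche
    model, serial transplants, and MiSeq-style reads with PCR bias,
    substitution error and index hopping) with exact ground truth; extracts
    barcodes from FASTQ by anchor-delimited matching; calls clones with a
    read-fraction detection threshold, single-base-error collapse and
    cross-sample contamination removal; and computes clonal statistics
    (Nei gene diversity H and differentiation index G, richness and dominance
    metrics, serial-transplant persistence, multi-organ sharing, and
    engrafting-cell frequencies from limiting-dilution transplants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
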