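Package: psiCNN
Title: Convolutional Sequence Modeling of RNA Pseudouridylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts RNA pseudouridylation (Psi) sites from local sequence
    context with a small convolutional neural network trained on 101-nt
    windows centered on uridines. Implements the full workflow: construction
    of positive and nearest-non-overlapping-thymine negative sample sets from
    site coordinates and reference sequences, one-hot encoding, network
    training with SGD/momentum/dropout/batch normalization/early stopping,
    plain and nested cross-validation with grid search, ROC/AUC and
    confusion-based evaluation, extraction of sequence motifs from first-layer
    convolution filters as position weight matrices, transcriptome-wide
    per-uridine scoring (lPPS), a transcript-level pseudouridylation potential
    score (tPPS), allele fold change of pseudouridylation potential (AFCP)
    for single-nucleotide variants, and a seeded planted-motif synthetic data
    generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
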