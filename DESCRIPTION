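Package: chromdense
Title: Cell Type-Specific Chromatin Accessibility Prediction from
    Sequence and Transcription Factor Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts chromatin accessibility of fixed-width genomic loci
    across cell types by combining DNA sequence, scanned with a densely
    connected convolutional network, with a transcription factor (TF)
    feature formed as the element-wise product of per-TF maximum
    motif-binding scores and normalized TF expression.  Provides genome
    tiling and peak-based labelling, depth-normalized DNase-seq signal
    construction, cell type-level cross-validation, classification and
    regression network variants with ablation switches, precision-recall
    and correlation based evaluation statistics, gradient importance
    scores for TF prioritization, extraction of binding motifs from
    first-layer convolution kernels, deleterious scoring of personal
    genome variants, an l1-penalized phenotype regression, and a
    synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    glmnet,
    jsonlite,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
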