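Package: priorTRN
Title: Prior-Augmented Transcriptional Regulatory Network Inference with
    Weighted LASSO and StARS Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers transcriptional regulatory networks (TRNs) from gene
    expression by fitting per-gene sparse linear models of expression on
    transcription factor activities, with penalties reduced on interactions
    supported by a prior network built from chromatin accessibility peaks
    and motif occurrences. The regularization level is chosen by StARS
    subsampling instability, and edges are ranked by a stability plus
    partial-correlation confidence. Includes transcription factor activity
    estimation (mRNA or prior-based least squares), network trimming and
    combination, precision-recall benchmarking against gold standards,
    out-of-sample expression prediction, core-regulator and module/GWAS
    enrichment analyses, and a synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
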