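Package: backsplicer
Title: Dual-Branch Convolutional Prediction of CircRNA Back-Splicing Sites
    with Filter-Level Motif Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a paired splice-acceptor / splice-donor
    sequence context supports circRNA back-splicing, using a dual-branch
    one-dimensional convolutional network over one-hot encoded 100-nt
    windows (50 nt intron + 50 nt exon per site).  Includes the full
    dataset-construction rules (flank filtering, deduplication, canonical
    negative sampling over 2-3 exons, stratified k-fold splitting), a
    seeded planted-motif simulator for benchmarking, confusion-matrix and
    ranking metrics (ACC, AUC, MCC, sensitivity, specificity) with
    cross-validation and batch-normalization ablation harnesses, and a
    filter-interpretation pipeline that converts first-layer convolutional
    activations into position probability matrices, exports MEME minimal
    motif files, profiles positional occurrence densities around the
    splice site, and compares motif sets across species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
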