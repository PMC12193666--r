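Package: methylkmer
Title: CpG Methylation Prediction from Flanking-Sequence k-mer Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting the binary methylation
    status of CpG sites from the k-mer composition of their flanking genomic
    sequence. Reads FASTA genomes and bedMethyl-style percent-methylation
    tracks, counts a 349-motif vocabulary (all 1- to 4-mers plus a
    configurable set of hexamers) in 500 bp windows around each CG site,
    binarizes percent methylation at a beta cutoff, reduces features with a
    univariate K-best filter, and optionally passes them through one of three
    learned feature-analysis stages (autoencoder compression, GAN-based
    augmentation, multi-head attention re-weighting) before classification
    with a 1D-adapted UNet or one of three baselines (CNN, FFNN-KNN hybrid,
    residual network). Ships the full threshold-metric, ROC/PR, chi-square
    and Cohen's kappa evaluation suite and a synthetic planted-effect genome
    simulator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
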