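Package: dazzle
Title: Gene Regulatory Network Inference with Dropout Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers weighted gene regulatory networks from single-cell
    RNA-seq expression matrices using a variational autoencoder built on a
    linear structural equation model. Training is regularized by dropout
    augmentation (per-iteration injection of synthetic Bernoulli dropout
    plus an auxiliary dropout classifier) and stabilized by a delayed L1
    sparsity schedule on the adjacency matrix. Includes BEELINE-style
    evaluation statistics (AUPRC ratio, early precision ratio, AUROC), a
    synthetic-data generator matching the model's assumptions, and
    post-inference network analyses (per-gene regulation scores, local
    neighborhoods, cross-condition scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
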