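Package: imaae
Title: Supervised Batch-Effect Correction for Single-Cell RNA-Seq with
    Anchor-Mapped Adversarial Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Corrects batch effects in annotated multi-batch single-cell
    RNA-seq data by mapping every batch onto an anchor batch with an
    adversarial autoencoder: an encoder/decoder pair is trained to
    reconstruct each cell's anchor-batch target profile while a
    Wasserstein critic with gradient penalty shapes the latent code
    toward a standard Gaussian prior. Provides the full pipeline
    (filtering, highly-variable-gene selection, total-count
    normalisation, log transform, PCA, cross-batch mutual
    nearest-neighbour graphs), three anchor-selection modes, cell-type
    supervised training with a passthrough rule for types private to one
    batch, corrected expression and latent embeddings, integration
    metrics (silhouette, adjusted Rand index, normalised mutual
    information and their F1 combinations), and a multi-batch count
    simulator for closed-, partial- and open-set cell-type scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph
Config/testthat/edition: 3
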