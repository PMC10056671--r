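# imaae — supervised scRNA-seq batch correction with anchor-mapped adversarial autoencoders

Joint analysis of single-cell RNA-seq experiments produced at different
times, in different labs, or on different platforms is confounded by batch
effects: systematic, non-biological shifts in measured expression. Most
correction methods are unsupervised; when per-cell **cell-type annotations**
are available, they can do substantially better — especially in *partial*
and *open* settings where batches do not share the same set of cell types.

`imaae` implements the IMAAE approach: every batch is mapped onto an
**anchor batch** with an adversarial autoencoder, using the cell-type labels
to decide which cells should end up looking alike. It is aimed at
computational biologists integrating annotated multi-batch scRNA-seq data
who want both a corrected expression matrix (usable for differential
expression, since outputs are non-negative by construction) and a corrected
low-dimensional embedding of user-chosen size.

## The model

Given log-normalised expression `x` for a cell, the encoder produces a
latent code via the reparameterisation `z = mu(x) + exp(logvar(x)/2) * eps`,
`eps ~ N(0, I)`, and the decoder (terminal ReLU, hence non-negative output)
produces the corrected profile `x~ = D(z)`. Training couples three losses:

- reconstruction to the **mapped anchor target** `a(x)` (a same-cell-type
  profile in the anchor batch, chosen along a cross-batch mutual-nearest-
  neighbour graph or uniformly at random):
  `L_R = (1/n) * sum_i || a(x_i) - x~_i ||^2`
- a Wasserstein critic with gradient penalty on the latent code,
  `L_D = -E[D_c(z_prior)] + E[D_c(z_enc)] +
  lambda * E[(||grad D_c(z^)|| - 1)^2]`, with `z^` sampled uniformly on
  segments between prior draws and encoder outputs, pushing the latent
  distribution towards the `N(0, I)` prior;
- the generator term `L_G = -E[D_c(z_enc)]` on the encoder.

Anchor construction offers three modes: a synthetic **balanced** batch
(per-type cross-batch tuple means), the real batch with the largest pooled
standard deviation (**max_std**), or a user-chosen batch (**custom**).
Cells whose type occurs in only one batch are **passed through unchanged**
rather than mapped into regions of expression space where no target exists.

Integration quality is scored with the standard protocol: restrict to cell
types co-occurring in every batch, take the top 50 principal components of
the corrected matrix, and compute ASW, ARI and NMI against both the batch
and the cell-type labels, combined as
`F1 = 2 * (1 - s_batch) * s_celltype / ((1 - s_batch) + s_celltype)`
(higher is better on all three F1 scores).

## Worked example

The built-in simulator generates multi-batch counts with known cell types
and controllable batch distortions, so the whole pipeline runs without any
external data:

```r
library(imaae)

cfg <- list(
  simulation = list(seed = 1),                  # 3 batches x 4 types x 150 cells
  pipeline   = list(min_genes_per_cell = 10, n_hvg = 300, random_seed = 1),
  train      = list(latent_dim = 32, epochs = 30, batch_size = 256, seed = 1)
)
res <- run_all(cfg)

before <- evaluate_all(res$prep$matrix$values, res$prep$matrix$batch,
                       res$prep$matrix$cell_type, seed = 1)
print(before)      # uncorrected
print(res$report)  # corrected
```

which prints:

```
--- before correction ---
MetricReport (1800 cells, types: alpha, beta, delta, gamma)
  ASW  batch  0.5171  celltype  0.0943  F1 0.1578
  ARI  batch  1.0000  celltype  0.0700  F1 0.0000
  NMI  batch  1.0000  celltype  0.1701  F1 0.0000
--- after correction ---
MetricReport (1800 cells, types: alpha, beta, delta, gamma)
  ASW  batch -0.0085  celltype  0.7630  F1 0.8687
  ARI  batch -0.0010  celltype  1.0000  F1 1.0005
  NMI  batch  0.0000  celltype  1.0000  F1 1.0000
```

Before correction the batches are clearly separated (batch ASW 0.52; a
k-means partition of the embedding recovers the batches exactly, ARI 1.0)
and the cell types are smeared (cell-type ASW 0.09). After correction the
batches are indistinguishable (batch scores ~0), the four cell types are
cleanly resolved (cell-type ASW 0.76, ARI/NMI 1.0), and all three F1 scores
rise accordingly. `res$correction` holds the corrected expression matrix
(log scale; `corrected_counts_scale()` back-transforms) and the latent
embedding; `export_embedding(res$correction, k)` yields a k-dimensional
embedding.

A thin command-line front-end with `simulate | preprocess | correct |
evaluate | run-all` subcommands is installed at `inst/cli/imaae.R`
(`system.file("cli", "imaae.R", package = "imaae")`).

## Documentation

The methods vignette (`vignettes/anchor-aae-batch-correction.Rmd`) describes
the model, its assumptions, every tunable parameter with its default and
rationale, what the simulator does and does not emulate, numerical choices,
and known limitations.
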