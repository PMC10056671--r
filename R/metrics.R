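#' @title Integration quality metrics
#' @description
#' The evaluation protocol: restrict to cell types co-occurring in every
#' batch, take the top 50 principal components of the corrected expression
#' matrix, then score average silhouette width (ASW), adjusted Rand index
#' (ARI) and normalised mutual information (NMI) against both the batch and
#' the cell-type labels, combining each batch/cell-type pair into an F1
#' score. Low batch-axis scores mean good mixing; high cell-type-axis scores
#' mean preserved biology; the F1 rewards both at once.
#' @name metrics
NULL

#' Restrict to cell types co-occurring in every batch
#'
#' @param batch,cell_type Per-cell labels.
#' @return Integer vector of cell indices whose type is present in all
#'   batches; errors if no type is universally shared.
#' @export
restrict_cooccurring <- function(batch, cell_type) {
  batch <- factor(batch); cell_type <- factor(cell_type)
  if (nlevels(batch) < 2) stop("need at least two batches")
  tab <- table(cell_type, batch) > 0
  shared <- rownames(tab)[rowSums(tab) == nlevels(batch)]
  if (!length(shared))
    stop("no cell type is shared by every batch; nothing to evaluate")
  which(cell_type %in% shared)
}

#' Top principal components of a corrected expression matrix
#'
#' @param x Cells x genes matrix (or `AnnotatedMatrix`).
#' @param n Number of components (50 by default, capped by the data rank).
#' @return Cells x n embedding.
#' @export
top_pcs <- function(x, n = 50) {
  if (inherits(x, "AnnotatedMatrix")) x <- x$values
  compute_pca(x, min(n, dim(x)))$embedding
}

#' Average silhouette width
#'
#' Mean silhouette coefficient over all points, Euclidean distance. Ranges
#' over \[-1, 1\]; near 0 for a label that is well mixed through the
#' embedding, near 1 for compact well-separated label groups.
#'
#' @param embedding Points x dims matrix.
#' @param labels One label per point; at least two distinct values.
#' @return Scalar ASW.
#' @export
asw <- function(embedding, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("silhouette needs at least two distinct labels")
  sil <- cluster::silhouette(as.integer(labels),
                             stats::dist(as.matrix(embedding)))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting Rand index adjusted for chance agreement via the
#' permutation-model expectation; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI in \[-1, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  ct <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  n2 <- comb2(sum(ct))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalised mutual information between two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two label
#' entropies (natural logarithms); 1 for identical partitions, 0 for
#' independent ones. If both partitions are single-class the NMI is defined
#' as 1.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar NMI in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  ct <- table(labels_a, labels_b) / n
  pa <- rowSums(ct); pb <- colSums(ct)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pa); hb <- h(pb)
  if (ha + hb == 0) return(1)
  outer_p <- outer(pa, pb)
  nz <- ct > 0
  mi <- sum(ct[nz] * log(ct[nz] / outer_p[nz]))
  mi / ((ha + hb) / 2)
}

#' Cluster an embedding for the partition-comparison metrics
#'
#' ARI and NMI compare the ground-truth labels with a clustering of the
#' embedding; this produces that clustering with k-means (10 random
#' restarts, fixed seed, so the metric protocol is pure).
#'
#' @param embedding Points x dims matrix.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param seed RNG seed for the restarts.
#' @return Integer cluster labels.
#' @export
cluster_for_label_metrics <- function(embedding, k, seed = 1L) {
  embedding <- as.matrix(embedding)
  if (k > nrow(embedding))
    stop("k (", k, ") exceeds the number of cells (", nrow(embedding), ")")
  if (k == nrow(embedding)) return(seq_len(nrow(embedding)))
  set.seed(seed)
  stats::kmeans(embedding, centers = k, nstart = 10,
                iter.max = 100)$cluster
}

#' Combine a batch score and a cell-type score into an F1 score
#'
#' `2 * (1 - b) * c / ((1 - b) + c)` with `b` the batch-axis score (lower is
#' better: good mixing) and `c` the cell-type-axis score (higher is better:
#' preserved structure). Applied identically to the ASW, ARI and NMI pairs.
#'
#' @param score_batch Batch-axis score `b`.
#' @param score_celltype Cell-type-axis score `c`.
#' @return Scalar F1.
#' @export
f1_combine <- function(score_batch, score_celltype) {
  denom <- (1 - score_batch) + score_celltype
  if (any(denom == 0)) stop("F1 undefined: zero denominator")
  2 * (1 - score_batch) * score_celltype / denom
}

#' Full evaluation report for a correction result
#'
#' Restricts to universally co-occurring cell types, extracts the top
#' `n_pcs` principal components of the corrected expression, and computes
#' ASW on both label axes, ARI/NMI between a k-means partition (k = number
#' of classes on the scored axis) and each label axis, and the three F1
#' combinations.
#'
#' @param corrected A `CorrectionResult`, or a plain cells x genes matrix.
#' @param batch,cell_type Per-cell labels aligned with the rows.
#' @param n_pcs Number of principal components (default 50).
#' @param seed Seed for the k-means partitions.
#' @return A `MetricReport` list: `asw_batch`, `asw_celltype`, `ari_batch`,
#'   `ari_celltype`, `nmi_batch`, `nmi_celltype`, `f1_asw`, `f1_ari`,
#'   `f1_nmi`, `n_cells_evaluated`, `celltypes_used`.
#' @export
evaluate_all <- function(corrected, batch, cell_type, n_pcs = 50,
                         seed = 1L) {
  x <- if (inherits(corrected, "CorrectionResult"))
    corrected$corrected_expression else as.matrix(corrected)
  stopifnot(nrow(x) == length(batch), length(batch) == length(cell_type))
  keep <- restrict_cooccurring(batch, cell_type)
  x <- x[keep, , drop = FALSE]
  b <- droplevels(factor(batch)[keep])
  t <- droplevels(factor(cell_type)[keep])
  emb <- top_pcs(x, n_pcs)
  asw_b <- asw(emb, b)
  asw_t <- asw(emb, t)
  km_b <- cluster_for_label_metrics(emb, nlevels(b), seed)
  km_t <- cluster_for_label_metrics(emb, nlevels(t), seed)
  ari_b <- ari(b, km_b); ari_t <- ari(t, km_t)
  nmi_b <- nmi(b, km_b); nmi_t <- nmi(t, km_t)
  structure(list(asw_batch = asw_b, asw_celltype = asw_t,
                 ari_batch = ari_b, ari_celltype = ari_t,
                 nmi_batch = nmi_b, nmi_celltype = nmi_t,
                 f1_asw = f1_combine(asw_b, asw_t),
                 f1_ari = f1_combine(ari_b, ari_t),
                 f1_nmi = f1_combine(nmi_b, nmi_t),
                 n_cells_evaluated = length(keep),
                 celltypes_used = levels(t)),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("MetricReport (", x$n_cells_evaluated, " cells, types: ",
      paste(x$celltypes_used, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  ASW  batch % .4f  celltype % .4f  F1 %.4f\n",
              x$asw_batch, x$asw_celltype, x$f1_asw))
  cat(sprintf("  ARI  batch % .4f  celltype % .4f  F1 %.4f\n",
              x$ari_batch, x$ari_celltype, x$f1_ari))
  cat(sprintf("  NMI  batch % .4f  celltype % .4f  F1 %.4f\n",
              x$nmi_batch, x$nmi_celltype, x$f1_nmi))
  invisible(x)
}
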