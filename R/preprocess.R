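#' Filter cells and genes by expression support
#'
#' Two-pass filter on raw counts: cells expressing (count > 0) fewer than
#' `min_genes_per_cell` genes — counted on the original gene set — are
#' removed first; genes expressed in fewer than `min_cells_per_gene` of the
#' retained cells are removed second. Ordering of survivors is preserved.
#'
#' @param m An [annotated_matrix()] with `layer_tag = "raw_counts"`.
#' @param min_genes_per_cell Cells expressing fewer genes than this are
#'   dropped (strictly-less-than rule: a cell expressing exactly the
#'   threshold is kept).
#' @param min_cells_per_gene Genes expressed in fewer retained cells than
#'   this are dropped.
#' @return The filtered `AnnotatedMatrix`.
#' @export
filter_cells_genes <- function(m, min_genes_per_cell = 600,
                               min_cells_per_gene = 3) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  if (m$layer_tag != "raw_counts")
    stop("filtering expects raw counts, got layer_tag '", m$layer_tag, "'")
  genes_per_cell <- rowSums(m$values > 0)
  keep_cells <- which(genes_per_cell >= min_genes_per_cell)
  if (!length(keep_cells))
    stop("all cells removed by the min_genes_per_cell=", min_genes_per_cell,
         " filter; lower the threshold")
  cells_per_gene <- colSums(m$values[keep_cells, , drop = FALSE] > 0)
  keep_genes <- which(cells_per_gene >= min_cells_per_gene)
  if (!length(keep_genes))
    stop("all genes removed by the min_cells_per_gene=", min_cells_per_gene,
         " filter; lower the threshold")
  subset_annotated(m, keep_cells, keep_genes)
}

# Internal: normalised-dispersion HVG statistic. Dispersion (variance/mean)
# of log1p(total-count-normalised) expression, standardised as the residual
# from a robust local regression of log-dispersion on mean expression.
# A robust global trend is preferred over within-bin z-scoring because truly
# variable genes can monopolise a mean bin, where a bin-local z-score of
# ~0 would hide them; the symmetric-family loess downweights them as
# outliers instead. Constant genes get -Inf so they are never selected.
hvg_dispersion <- function(values, target_sum = 20000) {
  sf <- rowSums(values)
  sf[sf == 0] <- 1
  norm <- log1p(values / sf * target_sum)
  mu <- colMeans(norm)
  v <- apply(norm, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  usable <- which(disp > 0)
  z <- rep(-Inf, length(disp))
  if (length(usable) >= 20) {
    y <- log(disp[usable])
    fit <- tryCatch(
      stats::loess(y ~ mu[usable], span = 0.75, degree = 2,
                   family = "symmetric"),
      error = function(e) NULL)
    z[usable] <- if (is.null(fit)) y else y - stats::fitted(fit)
  } else if (length(usable)) {
    z[usable] <- log(disp[usable])
  }
  const <- apply(values, 2, function(col) all(col == col[1]))
  z[const | v == 0] <- -Inf
  list(z = z, disp = disp)
}

#' Select highly variable genes
#'
#' Ranks genes by a normalised dispersion statistic — variance/mean of
#' log1p total-count-normalised expression, standardised against a robust
#' local-regression trend of log-dispersion on mean expression — and keeps
#' the top `n_hvg`. The statistic is computed on a transformed copy but the
#' returned matrix keeps the input's values and layer tag; gene order is
#' preserved.
#'
#' @param m A filtered `AnnotatedMatrix`.
#' @param n_hvg Number of genes to keep; must not exceed the gene count.
#' @return `m` restricted to the selected genes.
#' @export
select_hvg <- function(m, n_hvg = 2000) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  p <- ncol(m$values)
  if (n_hvg > p)
    stop("n_hvg (", n_hvg, ") exceeds the number of genes (", p, ")")
  score <- hvg_dispersion(m$values)
  top <- order(score$z, score$disp, decreasing = TRUE)[seq_len(n_hvg)]
  subset_annotated(m, genes = sort(top))
}

#' Normalise each cell to a common total count
#'
#' Scales every row so it sums to `target_sum` (20,000 by default).
#' Idempotent: normalising an already-normalised matrix changes nothing.
#'
#' @param m An `AnnotatedMatrix`; every cell must have a positive total.
#' @param target_sum Per-cell total after scaling.
#' @return The normalised matrix, `layer_tag = "normalized"`.
#' @export
normalize_total <- function(m, target_sum = 20000) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  totals <- rowSums(m$values)
  if (any(totals <= 0))
    stop("cell(s) with zero total count (first: ",
         m$cell_ids[which(totals <= 0)[1]],
         "); filter cells before normalising")
  out <- m
  out$values <- m$values / totals * target_sum
  out$layer_tag <- "normalized"
  out
}

#' Log-transform expression values
#'
#' Elementwise natural `log(x + 1)`; zeros map to zeros.
#'
#' @param m An `AnnotatedMatrix` with non-negative values.
#' @return The transformed matrix, `layer_tag = "lognormalized"`.
#' @export
log1p_transform <- function(m) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  if (min(m$values) < 0) stop("log1p requires non-negative values")
  out <- m
  out$values <- log1p(m$values)
  out$layer_tag <- "lognormalized"
  out
}

#' Principal component analysis of log-normalised expression
#'
#' Mean-centred (but not variance-scaled) PCA via singular value
#' decomposition.
#'
#' @param m An `AnnotatedMatrix`, normally log-normalised.
#' @param n_components Number of components, at most `min(cells, genes)`.
#' @return A `PCAResult`: list with `embedding` (cells x n_components),
#'   `components` (n_components x genes, orthonormal rows) and
#'   `explained_variance` (non-increasing).
#' @export
compute_pca <- function(m, n_components = 50) {
  x <- if (inherits(m, "AnnotatedMatrix")) m$values else as.matrix(m)
  if (n_components > min(dim(x)))
    stop("n_components (", n_components, ") exceeds min(cells, genes) = ",
         min(dim(x)))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(embedding = unname(pc$x[, seq_len(n_components),
                                         drop = FALSE]),
                 components = unname(t(pc$rotation[, seq_len(n_components),
                                                   drop = FALSE])),
                 explained_variance = pc$sdev[seq_len(n_components)]^2),
            class = "PCAResult")
}

#' Cross-batch same-type mutual nearest-neighbour graph
#'
#' For every pair of distinct batches and every cell type present in both,
#' connects each type-matched cell to its `k` nearest (Euclidean, in PCA
#' space) same-type cells of the other batch, keeping only mutual pairs.
#' Every edge therefore joins two cells of identical type in different
#' batches; there are no self or duplicate edges. Distance ties break on the
#' lower cell index.
#'
#' @param pca A `PCAResult` (or a plain embedding matrix) over all cells.
#' @param batch,cell_type Per-cell labels, aligned with the embedding rows.
#' @param k Neighbour count per batch pair; capped (with a warning) at the
#'   number of available candidates.
#' @return A `ConnectivityGraph`: list with `edges` (2-column matrix of cell
#'   indices, smaller index first) and `metadata` (data frame with
#'   `batch_a`, `batch_b`, `cell_type` per edge).
#' @export
build_cross_batch_graph <- function(pca, batch, cell_type, k = 5) {
  emb <- if (inherits(pca, "PCAResult")) pca$embedding else as.matrix(pca)
  stopifnot(k >= 1, nrow(emb) == length(batch),
            length(batch) == length(cell_type))
  batch <- factor(batch)
  cell_type <- factor(cell_type)
  batches <- levels(batch)
  edges <- list()
  meta <- list()
  for (i in seq_along(batches)) for (j in seq_along(batches)) {
    if (j <= i) next
    for (t in levels(cell_type)) {
      ia <- which(batch == batches[i] & cell_type == t)
      ib <- which(batch == batches[j] & cell_type == t)
      if (!length(ia) || !length(ib)) next
      kk <- min(k, length(ia), length(ib))
      if (kk < k)
        warning("k=", k, " capped at ", kk, " for type '", t, "' between ",
                batches[i], " and ", batches[j])
      d <- as.matrix(stats::dist(emb[c(ia, ib), , drop = FALSE]))
      d <- d[seq_along(ia), length(ia) + seq_along(ib), drop = FALSE]
      # nearest kk of B for each A-cell and vice versa; ties -> lower index
      nn_ab <- apply(d, 1, function(r) order(r, seq_along(r))[seq_len(kk)],
                     simplify = FALSE)
      nn_ba <- apply(d, 2, function(r) order(r, seq_along(r))[seq_len(kk)],
                     simplify = FALSE)
      for (a in seq_along(ia)) for (b in nn_ab[[a]]) {
        if (a %in% nn_ba[[b]]) {
          e <- sort(c(ia[a], ib[b]))
          edges[[length(edges) + 1L]] <- e
          meta[[length(meta) + 1L]] <-
            data.frame(batch_a = batches[i], batch_b = batches[j],
                       cell_type = t)
        }
      }
    }
  }
  if (length(edges)) {
    edge_mat <- do.call(rbind, edges)
    meta_df <- do.call(rbind, meta)
  } else {
    edge_mat <- matrix(integer(), ncol = 2)
    meta_df <- data.frame(batch_a = character(), batch_b = character(),
                          cell_type = character())
  }
  structure(list(edges = edge_mat, metadata = meta_df),
            class = "ConnectivityGraph")
}

#' Run the standard preprocessing chain
#'
#' Fixed order: filter, highly-variable-gene selection, total-count
#' normalisation, log1p, and optionally PCA plus the cross-batch graph.
#' The HVG statistic is computed on a temporarily normalised copy; the raw
#' counts are then subset to the selected genes before normalisation so the
#' target total applies to the analysed gene set.
#'
#' @param m Raw-count `AnnotatedMatrix`.
#' @param config A [pipeline_config()].
#' @param with_graph Build the PCA embedding and connectivity graph (the two
#'   optional steps); when `FALSE` downstream mappings fall back to random
#'   same-type pairing.
#' @return List with `matrix` (log-normalised `AnnotatedMatrix`), and — when
#'   `with_graph` — `pca` and `graph`.
#' @export
preprocess <- function(m, config = pipeline_config(),
                       with_graph = config$use_graph_mapping) {
  m <- filter_cells_genes(m, config$min_genes_per_cell,
                          config$min_cells_per_gene)
  m <- select_hvg(m, min(config$n_hvg, ncol(m$values)))
  m <- normalize_total(m, config$target_sum)
  m <- log1p_transform(m)
  out <- list(matrix = m)
  if (with_graph) {
    npc <- min(config$n_pcs_graph, dim(m$values) - 1L)
    out$pca <- compute_pca(m, npc)
    out$graph <- build_cross_batch_graph(out$pca, m$batch, m$cell_type,
                                         config$graph_k)
  }
  out
}
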