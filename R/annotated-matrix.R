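#' Annotated expression matrix
#'
#' The universal data carrier of the pipeline: a cells x genes expression
#' matrix together with per-cell batch and cell-type labels. All functions in
#' the package consume and return this container. Values are always oriented
#' cells x genes internally; rows are cells.
#'
#' @param values Numeric matrix, cells x genes, finite and non-negative.
#' @param cell_ids Character vector of unique cell identifiers (one per row).
#' @param gene_ids Character vector of unique gene identifiers (one per column).
#' @param batch Per-cell batch label (coerced to factor).
#' @param cell_type Per-cell cell-type annotation (coerced to factor). The
#'   method is supervised: every cell must carry a type label.
#' @param layer_tag One of `"raw_counts"`, `"normalized"`, `"lognormalized"`;
#'   records which transform the values are in.
#'
#' @return An object of class `AnnotatedMatrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `batch`, `cell_type`, `layer_tag`.
#' @export
annotated_matrix <- function(values, cell_ids, gene_ids, batch, cell_type,
                             layer_tag = c("raw_counts", "normalized",
                                           "lognormalized")) {
  layer_tag <- match.arg(layer_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- structure(
    list(values = values,
         cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids),
         batch = factor(batch),
         cell_type = factor(cell_type),
         layer_tag = layer_tag),
    class = "AnnotatedMatrix")
  validate_annotated_matrix(m)
  m
}

#' Validate an AnnotatedMatrix
#'
#' Checks the container invariants: consistent dimensions, unique identifiers,
#' finite non-negative values, and a label for every cell.
#'
#' @param m An `AnnotatedMatrix`.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_annotated_matrix <- function(m) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  n <- nrow(m$values)
  p <- ncol(m$values)
  if (length(m$cell_ids) != n)
    stop("cell_ids length (", length(m$cell_ids),
         ") does not match number of rows (", n, ")")
  if (length(m$gene_ids) != p)
    stop("gene_ids length (", length(m$gene_ids),
         ") does not match number of columns (", p, ")")
  if (length(m$batch) != n)
    stop("batch length does not match number of cells")
  if (length(m$cell_type) != n)
    stop("cell_type length does not match number of cells")
  dup <- m$cell_ids[duplicated(m$cell_ids)]
  if (length(dup))
    stop("duplicate cell ids are not allowed; first duplicate: ", dup[1])
  dup <- m$gene_ids[duplicated(m$gene_ids)]
  if (length(dup))
    stop("duplicate gene ids are not allowed; first duplicate: ", dup[1])
  if (anyNA(m$batch))
    stop("missing batch label for ", sum(is.na(m$batch)), " cell(s)")
  if (anyNA(m$cell_type))
    stop("missing cell_type label for ", sum(is.na(m$cell_type)),
         " cell(s); the method is supervised and requires a type per cell")
  if (n > 0 && p > 0) {
    if (!all(is.finite(m$values)))
      stop("values contain non-finite entries")
    if (min(m$values) < 0)
      stop("values must be non-negative for layer_tag '", m$layer_tag, "'")
  }
  invisible(m)
}

#' @export
print.AnnotatedMatrix <- function(x, ...) {
  cat("AnnotatedMatrix: ", nrow(x$values), " cells x ", ncol(x$values),
      " genes [", x$layer_tag, "]\n", sep = "")
  cat("  batches:   ", paste(levels(x$batch), collapse = ", "), "\n", sep = "")
  cat("  cell types:", paste(levels(x$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.AnnotatedMatrix <- function(x) dim(x$values)

# Internal: subset by cell and/or gene index, keeping labels in step and
# dropping unused factor levels.
subset_annotated <- function(m, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(m$values))
  if (is.null(genes)) genes <- seq_len(ncol(m$values))
  structure(
    list(values = m$values[cells, genes, drop = FALSE],
         cell_ids = m$cell_ids[cells],
         gene_ids = m$gene_ids[genes],
         batch = droplevels(m$batch[cells]),
         cell_type = droplevels(m$cell_type[cells]),
         layer_tag = m$layer_tag),
    class = "AnnotatedMatrix")
}
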