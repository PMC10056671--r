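#' Read an annotated expression matrix from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx_dir`}{a directory holding `matrix.mtx` (MatrixMarket sparse
#'     triplets), `barcodes.tsv` (cell ids), `features.tsv` (gene ids),
#'     `annotations.tsv` (columns `cell_id`, `batch`, `cell_type`) and an
#'     optional `meta.json` carrying the layer tag.}
#'   \item{`delimited`}{a single TSV/CSV with a header row of gene ids and the
#'     cell id in the first column, plus sidecar files
#'     `<path>.annotations.tsv` and `<path>.meta.json`.}
#' }
#' Matrices are oriented cells x genes internally. On-disk genes x cells
#' layouts are accepted only with `orientation = "genes_by_cells"`.
#'
#' @param path Directory (`mtx_dir`) or file (`delimited`) to read.
#' @param format One of `"mtx_dir"`, `"delimited"`.
#' @param orientation On-disk orientation, `"cells_by_genes"` (default) or
#'   `"genes_by_cells"` (the matrix is transposed on read).
#' @return An [annotated_matrix()].
#' @export
read_matrix <- function(path, format = c("mtx_dir", "delimited"),
                        orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("directory not found: ", path)
    mtx_file <- file.path(path, "matrix.mtx")
    for (f in c(mtx_file, file.path(path, c("barcodes.tsv", "features.tsv",
                                            "annotations.tsv"))))
      if (!file.exists(f)) stop("missing file in mtx_dir: ", f)
    values <- as.matrix(Matrix::readMM(mtx_file))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    features <- readLines(file.path(path, "features.tsv"))
    if (orientation == "genes_by_cells") values <- t(values)
    ann <- read_annotations(file.path(path, "annotations.tsv"))
    meta_file <- file.path(path, "meta.json")
    layer_tag <- if (file.exists(meta_file))
      jsonlite::read_json(meta_file)$layer_tag else "raw_counts"
    assemble_matrix(values, barcodes, features, ann, layer_tag)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, colClasses = "character")
    ids <- tab[[1]]
    other_ids <- colnames(tab)[-1]
    raw <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop("non-numeric value '", raw[bad[1], bad[2]], "' at row ", bad[1],
           ", column ", bad[2], " of ", path)
    }
    if (orientation == "genes_by_cells") {
      num <- t(num)
      barcodes <- other_ids; features <- ids
    } else {
      barcodes <- ids; features <- other_ids
    }
    ann <- read_annotations(paste0(path, ".annotations.tsv"))
    meta_file <- paste0(path, ".meta.json")
    layer_tag <- if (file.exists(meta_file))
      jsonlite::read_json(meta_file)$layer_tag else "raw_counts"
    assemble_matrix(num, barcodes, features, ann, layer_tag)
  }
}

read_annotations <- function(file) {
  if (!file.exists(file)) stop("missing annotation table: ", file)
  ann <- utils::read.table(file, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  for (col in c("cell_id", "batch", "cell_type"))
    if (!col %in% colnames(ann))
      stop("annotation table ", file, " is missing required column '",
           col, "'")
  ann
}

assemble_matrix <- function(values, barcodes, features, ann, layer_tag) {
  idx <- match(barcodes, ann$cell_id)
  if (anyNA(idx))
    stop("annotation table has no row for cell id '",
         barcodes[which(is.na(idx))[1]], "'")
  annotated_matrix(values, barcodes, features,
                   batch = ann$batch[idx], cell_type = ann$cell_type[idx],
                   layer_tag = layer_tag)
}

#' Write an annotated expression matrix to disk
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(m))` reproduces `m`
#' exactly for integer counts and within floating-point round-trip precision
#' otherwise. The MatrixMarket file stores only the non-zero entries.
#'
#' @param m An [annotated_matrix()].
#' @param path Output directory (`mtx_dir`) or file (`delimited`).
#' @param format One of `"mtx_dir"`, `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("mtx_dir", "delimited")) {
  format <- match.arg(format)
  validate_annotated_matrix(m)
  ann <- data.frame(cell_id = m$cell_ids, batch = as.character(m$batch),
                    cell_type = as.character(m$cell_type))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    writeLines(m$gene_ids, file.path(path, "features.tsv"))
    utils::write.table(ann, file.path(path, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(layer_tag = m$layer_tag),
                         file.path(path, "meta.json"), auto_unbox = TRUE)
  } else {
    tab <- data.frame(cell_id = m$cell_ids, check.names = FALSE)
    vals <- as.data.frame(m$values)
    colnames(vals) <- m$gene_ids
    tab <- cbind(tab, vals)
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    utils::write.table(format(tab, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = sep, quote = FALSE, row.names = FALSE)
    utils::write.table(ann, paste0(path, ".annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(layer_tag = m$layer_tag),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Holds the preprocessing thresholds and graph parameters. Defaults follow
#' the published protocol: cells expressing fewer than 600 genes and genes
#' expressed in fewer than 3 cells are removed, 2000 highly variable genes are
#' kept, and every cell is scaled to a total count of 20,000.
#'
#' @param min_genes_per_cell Minimum number of expressed genes per cell.
#' @param min_cells_per_gene Minimum number of expressing cells per gene.
#' @param n_hvg Number of highly variable genes to keep.
#' @param target_sum Per-cell total count after normalisation.
#' @param n_pcs_graph Number of principal components for graph construction.
#' @param graph_k Mutual nearest-neighbour count per batch pair.
#' @param use_graph_mapping Build the cross-batch graph and use it for
#'   anchor mapping (otherwise mappings are sampled uniformly at random).
#' @param random_seed Seed used by downstream stochastic stages.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(min_genes_per_cell = 600,
                            min_cells_per_gene = 3,
                            n_hvg = 2000,
                            target_sum = 20000,
                            n_pcs_graph = 50,
                            graph_k = 5,
                            use_graph_mapping = TRUE,
                            random_seed = 1L) {
  cfg <- list(min_genes_per_cell = as.integer(min_genes_per_cell),
              min_cells_per_gene = as.integer(min_cells_per_gene),
              n_hvg = as.integer(n_hvg),
              target_sum = as.numeric(target_sum),
              n_pcs_graph = as.integer(n_pcs_graph),
              graph_k = as.integer(graph_k),
              use_graph_mapping = isTRUE(use_graph_mapping),
              random_seed = as.integer(random_seed))
  for (key in c("min_genes_per_cell", "min_cells_per_gene", "n_hvg",
                "n_pcs_graph", "graph_k", "target_sum"))
    if (is.na(cfg[[key]]) || cfg[[key]] <= 0)
      stop("configuration value '", key, "' must be positive")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from a YAML key-value file
#'
#' Keys are exactly the [pipeline_config()] argument names; unspecified keys
#' take their defaults. Unknown keys are an error.
#'
#' @param path Path to the YAML (key: value) file.
#' @return A `PipelineConfig`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
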