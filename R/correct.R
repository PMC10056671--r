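#' Apply a trained model to correct batch effects
#'
#' Non-passthrough cells are replaced by `decode(encode_mu(x))`, the decoder
#' applied to the mean latent code (`eps = 0` at inference, so correction is
#' reproducible); passthrough cells — types private to a single batch — are
#' copied through bit-identically. The latent embedding is `encode_mu(x)`
#' for *all* cells, passthrough included.
#'
#' @param model A `TrainedAAE`.
#' @param m The preprocessed `AnnotatedMatrix` (same gene set and transforms
#'   as the training data).
#' @param mapping The [build_training_mapping()] result carrying the
#'   passthrough mask.
#' @param sample_latent Draw a stochastic latent instead of the mean code
#'   (off by default; corrections should be reproducible).
#' @return A `CorrectionResult`: list with `corrected_expression`
#'   (cells x genes, non-negative, log-normalised scale), `latent`
#'   (cells x latent_dim), `passthrough_mask`, and `provenance`.
#' @export
apply_correction <- function(model, m, mapping, sample_latent = FALSE) {
  stopifnot(inherits(model, "TrainedAAE"), inherits(m, "AnnotatedMatrix"))
  if (!identical(model$gene_ids, m$gene_ids)) {
    missing <- setdiff(model$gene_ids, m$gene_ids)
    stop("gene set does not match the trained model",
         if (length(missing)) paste0("; missing genes: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..."))
  }
  enc <- aae_encode(model, m$values, sample = sample_latent)
  corrected <- m$values
  pt <- mapping$passthrough_mask
  if (any(!pt))
    corrected[!pt, ] <- aae_decode(model, enc$z[!pt, , drop = FALSE])
  structure(list(corrected_expression = corrected,
                 latent = enc$mu,
                 passthrough_mask = pt,
                 provenance = list(config = model$config,
                                   model_hash = param_hash(model))),
            class = "CorrectionResult")
}

# Cheap deterministic fingerprint of the model parameters.
param_hash <- function(model) {
  v <- unlist(lapply(c(model$encoder$trunk, list(model$encoder$mu,
                                                 model$encoder$logvar),
                       model$decoder), function(l) c(l$W, l$b)))
  sprintf("%.8e", sum(v * seq_along(v) %% 97))
}

#' Export a low-dimensional embedding from a correction result
#'
#' Returns the latent embedding itself when `n_dims` equals the latent
#' dimension, otherwise its first `n_dims` principal components. Dimensions
#' beyond the trained latent size cannot be exported — retrain with a larger
#' latent space instead (very small latent spaces merge nearby cell types,
#' so the latent dimension should not be set too low to begin with).
#'
#' @param r A `CorrectionResult`.
#' @param n_dims Requested embedding dimension, `1 <= n_dims <= latent_dim`.
#' @return Cells x `n_dims` matrix.
#' @export
export_embedding <- function(r, n_dims) {
  stopifnot(inherits(r, "CorrectionResult"))
  d <- ncol(r$latent)
  if (n_dims < 1) stop("n_dims must be at least 1")
  if (n_dims > d)
    stop("n_dims (", n_dims, ") exceeds the trained latent dimension (", d,
         "); retrain with a larger latent space")
  if (n_dims == d) return(r$latent)
  compute_pca(r$latent, n_dims)$embedding
}

#' Back-transform corrected expression to count scale
#'
#' The model operates in log1p space; this applies `expm1` for tools that
#' expect count-scale values.
#'
#' @param r A `CorrectionResult`.
#' @return Cells x genes matrix on the count scale.
#' @export
corrected_counts_scale <- function(r) {
  stopifnot(inherits(r, "CorrectionResult"))
  expm1(r$corrected_expression)
}
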