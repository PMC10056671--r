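#' @title Anchor construction and training mappings
#' @description
#' The anchor batch is the reference every other batch is transformed onto.
#' Three modes exist: a synthetic intermediate batch built from per-type
#' cross-batch tuple means (`balanced_mean`), the real batch with the largest
#' pooled standard deviation (`max_std`), or a user-chosen batch (`custom`).
#' `build_training_mapping()` then pairs every trainable cell with one anchor
#' profile of its own cell type; cells of types private to a single batch are
#' marked passthrough and excluded from both training and correction.
#' @name anchor
NULL

new_anchor_set <- function(profiles, types, mode, source_batch, max_per_type,
                           tuples = NULL) {
  structure(list(anchor_profiles = profiles,
                 anchor_types = factor(types),
                 mode = mode,
                 source_batch = source_batch,
                 max_per_type = as.integer(max_per_type),
                 tuples = tuples),
            class = "AnchorSet")
}

#' @export
print.AnchorSet <- function(x, ...) {
  cat("AnchorSet [", x$mode, "]: ", nrow(x$anchor_profiles), " profiles, ",
      nlevels(x$anchor_types), " cell types",
      if (!is.null(x$source_batch)) paste0(", source batch '",
                                           x$source_batch, "'"),
      "\n", sep = "")
  invisible(x)
}

# Internal: cell types present in >= 2 batches (the integrable types).
shared_types <- function(m) {
  tab <- table(m$cell_type, m$batch) > 0
  rownames(tab)[rowSums(tab) >= 2]
}

#' Build a balanced-mode intermediate anchor batch
#'
#' For every cell type shared by at least two batches, draws up to
#' `max_per_type` cross-batch tuples — one cell of that type from each batch
#' containing it — and emits the arithmetic mean expression vector of each
#' tuple as one anchor profile. When a connectivity graph is supplied, tuple
#' members are preferentially drawn along graph edges (a random seed cell,
#' then a graph neighbour in each other batch when one exists); otherwise
#' members are sampled uniformly. The resulting intermediate batch sits
#' between the real batches in expression space.
#'
#' @param m Log-normalised `AnnotatedMatrix`.
#' @param graph Optional [build_cross_batch_graph()] result.
#' @param max_per_type Per-type cap on the number of anchor profiles
#'   (downsampling keeps training cost bounded on large datasets).
#' @param seed Integer seed; the construction is deterministic given it.
#' @return An `AnchorSet` with `mode = "balanced_mean"`.
#' @export
select_anchor_balanced <- function(m, graph = NULL, max_per_type = 1000,
                                   seed = 1L) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  sh <- shared_types(m)
  if (!length(sh))
    stop("nothing to integrate: no cell type occurs in more than one batch")
  adj <- if (!is.null(graph) && nrow(graph$edges)) graph$edges else NULL
  profiles <- list(); types <- character(); tuples <- list()
  set.seed(seed)
  for (t in sh) {
    in_type <- m$cell_type == t
    batches_t <- levels(m$batch)[table(m$batch[in_type]) > 0]
    per_batch <- lapply(batches_t, function(b) which(in_type & m$batch == b))
    names(per_batch) <- batches_t
    n_tuples <- min(max_per_type, max(lengths(per_batch)))
    for (r in seq_len(n_tuples)) {
      seed_batch <- sample(length(per_batch), 1)
      seed_cell <- resample(per_batch[[seed_batch]], 1)
      members <- seed_cell
      for (b in seq_along(per_batch)) {
        if (b == seed_batch) next
        cand <- per_batch[[b]]
        pick <- NULL
        if (!is.null(adj)) {
          nb <- c(adj[adj[, 1] == seed_cell, 2], adj[adj[, 2] == seed_cell, 1])
          nb <- intersect(nb, cand)
          if (length(nb)) pick <- resample(nb, 1)
        }
        if (is.null(pick)) pick <- resample(cand, 1)
        members <- c(members, pick)
      }
      profiles[[length(profiles) + 1L]] <-
        colMeans(m$values[members, , drop = FALSE])
      types <- c(types, t)
      tuples[[length(tuples) + 1L]] <- members
    }
  }
  new_anchor_set(do.call(rbind, profiles), types, "balanced_mean",
                 NULL, max_per_type, tuples)
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, n) x[sample.int(length(x), n)]

# Internal: anchor set made of one real batch's cells, downsampled per type.
anchor_from_batch <- function(m, batch_id, mode, max_per_type, seed) {
  idx <- which(m$batch == batch_id)
  set.seed(seed)
  keep <- unlist(lapply(split(idx, droplevels(m$cell_type[idx])), function(v)
    if (length(v) > max_per_type) sort(resample(v, max_per_type)) else v),
    use.names = FALSE)
  keep <- sort(keep)
  new_anchor_set(m$values[keep, , drop = FALSE],
                 as.character(m$cell_type[keep]), mode,
                 as.character(batch_id), max_per_type,
                 tuples = as.list(keep))
}

#' Select the maximum-standard-deviation batch as the anchor
#'
#' Computes, per batch, the standard deviation of all log-normalised values
#' pooled over that batch's cells and genes; the batch with the largest
#' pooled standard deviation — taken as covering the most cell-state
#' variability — becomes the anchor. Ties break towards the batch with more
#' distinct cell types, then the lexicographically smaller batch id (with a
#' warning).
#'
#' @param m Log-normalised `AnnotatedMatrix` with at least two batches.
#' @param max_per_type Per-type downsampling cap on anchor cells.
#' @param seed Seed for the downsampling draw.
#' @return An `AnchorSet` with `mode = "max_std"` and `source_batch` set.
#' @export
select_anchor_max_std <- function(m, max_per_type = 1000, seed = 1L) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  if (nlevels(m$batch) < 2) stop("max_std mode needs at least two batches")
  sds <- vapply(levels(m$batch), function(b)
    stats::sd(m$values[m$batch == b, , drop = FALSE]), numeric(1))
  best <- which(sds == max(sds))
  if (length(best) > 1) {
    warning("pooled standard deviation tie between batches: ",
            paste(levels(m$batch)[best], collapse = ", "))
    ntypes <- vapply(levels(m$batch)[best], function(b)
      length(unique(m$cell_type[m$batch == b])), integer(1))
    best <- best[ntypes == max(ntypes)]
    best <- best[order(levels(m$batch)[best])][1]
  }
  anchor_from_batch(m, levels(m$batch)[best], "max_std", max_per_type, seed)
}

#' Use a user-chosen batch as the anchor
#'
#' @param m Log-normalised `AnnotatedMatrix`.
#' @param batch_id The batch to anchor on; must exist in `m`.
#' @param max_per_type Per-type downsampling cap on anchor cells.
#' @param seed Seed for the downsampling draw.
#' @return An `AnchorSet` with `mode = "custom"` and `source_batch` set.
#' @export
select_anchor_custom <- function(m, batch_id, max_per_type = 1000,
                                 seed = 1L) {
  stopifnot(inherits(m, "AnnotatedMatrix"))
  if (!batch_id %in% levels(m$batch))
    stop("unknown batch '", batch_id, "'; available: ",
         paste(levels(m$batch), collapse = ", "))
  anchor_from_batch(m, batch_id, "custom", max_per_type, seed)
}

#' Pair every trainable cell with an anchor target profile
#'
#' Cells whose type occurs in only one batch are passthrough: they are never
#' mapped and are copied unchanged through correction. Every other cell is
#' paired with one anchor profile of its own cell type — a graph-linked
#' profile when the anchor set records a tuple containing a graph neighbour
#' of the cell (or, for batch anchors, an anchor cell adjacent to it),
#' otherwise one drawn uniformly from the same-type profiles.
#'
#' Cells of a type that is shared across batches but absent from the anchor
#' set are an inconsistency: with `missing_type = "error"` (default) this
#' aborts; `missing_type = "transform"` instead marks them non-passthrough
#' but unmapped — they take no part in training yet are still transformed at
#' inference, the naive handling whose artefacts motivate the passthrough
#' rule and the autoencoder-only ablation.
#'
#' @param m Log-normalised `AnnotatedMatrix`.
#' @param anchors An `AnchorSet` built from `m`'s gene space.
#' @param graph Optional connectivity graph used for graph-linked pairing.
#' @param seed Seed for the uniform draws; pairing is deterministic given it.
#' @param missing_type Handling of shared types absent from the anchor.
#' @return A `TrainingMapping`: list with `pairs` (2-column matrix: cell
#'   index, anchor profile index), `passthrough_mask` (logical per cell) and
#'   `random_candidates` (per-type profile index list used for per-epoch
#'   resampling of the uniform pairings).
#' @export
build_training_mapping <- function(m, anchors, graph = NULL, seed = 1L,
                                   missing_type = c("error", "transform")) {
  stopifnot(inherits(m, "AnnotatedMatrix"), inherits(anchors, "AnchorSet"))
  missing_type <- match.arg(missing_type)
  if (ncol(anchors$anchor_profiles) != ncol(m$values))
    stop("anchor gene space (", ncol(anchors$anchor_profiles),
         ") does not match data gene space (", ncol(m$values), ")")
  n <- nrow(m$values)
  type_tab <- table(m$cell_type, m$batch) > 0
  n_batches_per_type <- rowSums(type_tab)
  passthrough <- n_batches_per_type[as.character(m$cell_type)] < 2
  names(passthrough) <- NULL
  anchor_by_type <- split(seq_len(nrow(anchors$anchor_profiles)),
                          anchors$anchor_types)
  # graph adjacency: cell -> neighbouring cells
  adj <- if (!is.null(graph) && nrow(graph$edges)) graph$edges else NULL
  # anchor profile index for each contributing cell (tuple membership)
  cell_to_profiles <- list()
  if (!is.null(anchors$tuples))
    for (p in seq_along(anchors$tuples))
      for (cell in anchors$tuples[[p]])
        cell_to_profiles[[as.character(cell)]] <-
          c(cell_to_profiles[[as.character(cell)]], p)
  set.seed(seed)
  cell_idx <- integer(); prof_idx <- integer(); fixed <- logical()
  unmapped <- logical(n)
  for (i in which(!passthrough)) {
    t <- as.character(m$cell_type[i])
    cand <- anchor_by_type[[t]]
    if (is.null(cand) || !length(cand)) {
      if (missing_type == "error")
        stop("internal consistency error: cell type '", t,
             "' occurs in multiple batches but has no anchor profile")
      unmapped[i] <- TRUE
      next
    }
    pick <- NULL; via_graph <- FALSE
    if (!is.null(adj)) {
      nb <- c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1])
      linked <- unique(unlist(cell_to_profiles[as.character(c(i, nb))]))
      linked <- intersect(linked, cand)
      if (length(linked)) { pick <- resample(linked, 1); via_graph <- TRUE }
    }
    if (is.null(pick)) pick <- resample(cand, 1)
    cell_idx <- c(cell_idx, i); prof_idx <- c(prof_idx, pick)
    fixed <- c(fixed, via_graph)
  }
  structure(list(pairs = cbind(cell = cell_idx, profile = prof_idx),
                 fixed = fixed,
                 passthrough_mask = passthrough,
                 unmapped = unmapped,
                 random_candidates = anchor_by_type,
                 cell_types = as.character(m$cell_type)),
            class = "TrainingMapping")
}

# Internal: redraw the uniform (non-graph-linked) pairings; used once per
# training epoch so random mappings are resampled while graph-linked ones
# stay fixed.
resample_mapping_pairs <- function(mapping) {
  pairs <- mapping$pairs
  redo <- which(!mapping$fixed)
  for (r in redo) {
    cand <- mapping$random_candidates[[mapping$cell_types[pairs[r, 1]]]]
    pairs[r, 2] <- resample(cand, 1)
  }
  pairs
}
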