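# Shared fixtures and independent oracles. Heavy fixtures (trained models)
# are cached per session so several test files can share one training run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A tiny hand-specified AnnotatedMatrix: 2 batches x 2 types, 4 genes.
tiny_matrix <- function() {
  values <- rbind(c(5, 0, 1, 2),
                  c(4, 1, 0, 3),
                  c(0, 6, 2, 1),
                  c(1, 5, 3, 0),
                  c(6, 0, 2, 1),
                  c(0, 7, 1, 2))
  annotated_matrix(values,
                   cell_ids = paste0("c", 1:6),
                   gene_ids = paste0("g", 1:4),
                   batch = c("b1", "b1", "b1", "b1", "b2", "b2"),
                   cell_type = c("t1", "t1", "t2", "t2", "t1", "t2"),
                   layer_tag = "raw_counts")
}

random_annotated <- function(n = 20, p = 10, density = 0.5, seed = 1,
                             integer_counts = TRUE) {
  set.seed(seed)
  vals <- matrix(stats::rbinom(n * p, 1, density) *
                   (if (integer_counts) stats::rpois(n * p, 5) + 1
                    else stats::rexp(n * p)), n, p)
  annotated_matrix(vals,
                   cell_ids = sprintf("cell%03d", seq_len(n)),
                   gene_ids = sprintf("g%03d", seq_len(p)),
                   batch = sample(c("A", "B"), n, replace = TRUE),
                   cell_type = sample(c("x", "y"), n, replace = TRUE),
                   layer_tag = "raw_counts")
}

# --- independent oracles -------------------------------------------------

# Pair-counting adjusted Rand index: exhaustive loop over all C(n,2) pairs.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Direct-entropy NMI oracle computed from explicit probability sums.
nmi_entropy_oracle <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  pa <- vapply(ua, function(u) sum(a == u) / n, numeric(1))
  pb <- vapply(ub, function(u) sum(b == u) / n, numeric(1))
  mi <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    pij <- sum(a == ua[i] & b == ub[j]) / n
    if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
  }
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  if (ha + hb == 0) return(1)
  mi / ((ha + hb) / 2)
}

# Brute-force mutual k-nearest-neighbour edges for one type across batches.
mutual_knn_oracle <- function(emb, batch, cell_type, k) {
  edges <- NULL
  batches <- sort(unique(batch))
  for (bi in seq_along(batches)) for (bj in seq_along(batches)) {
    if (bj <= bi) next
    for (t in unique(cell_type)) {
      ia <- which(batch == batches[bi] & cell_type == t)
      ib <- which(batch == batches[bj] & cell_type == t)
      if (!length(ia) || !length(ib)) next
      kk <- min(k, length(ia), length(ib))
      for (a in ia) for (b in ib) {
        da <- sqrt(colSums((t(emb[ib, , drop = FALSE]) - emb[a, ])^2))
        db <- sqrt(colSums((t(emb[ia, , drop = FALSE]) - emb[b, ])^2))
        ra <- order(da, seq_along(da))[seq_len(kk)]
        rb <- order(db, seq_along(db))[seq_len(kk)]
        if (which(ib == b) %in% ra && which(ia == a) %in% rb)
          edges <- rbind(edges, sort(c(a, b)))
      }
    }
  }
  if (is.null(edges)) matrix(integer(), ncol = 2) else
    edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# --- heavy shared fixtures ----------------------------------------------

# Full pipeline on the default closed-set simulation. mode in
# c("full", "gan_only"); returns before/after reports and pieces.
closed_run <- function(seed, mode = "full") {
  cached(paste0("closed_", seed, "_", mode), {
    m <- simulate_counts(simulation_config(seed = seed))
    prep <- preprocess(m, pipeline_config(min_genes_per_cell = 10,
                                          n_hvg = 300, random_seed = seed))
    a <- select_anchor_balanced(prep$matrix, prep$graph, 1000, seed)
    map <- build_training_mapping(prep$matrix, a, prep$graph, seed)
    fit <- train_aae(prep$matrix, map, a,
                     aae_config(ncol(prep$matrix$values), 32, epochs = 30,
                                batch_size = 256, seed = seed, mode = mode))
    corr <- apply_correction(fit, prep$matrix, map)
    list(prep = prep, anchors = a, mapping = map, fit = fit, corr = corr,
         before = evaluate_all(prep$matrix$values, prep$matrix$batch,
                               prep$matrix$cell_type, seed = seed),
         after = evaluate_all(corr, prep$matrix$batch,
                              prep$matrix$cell_type, seed = seed))
  })
}

# Partial-set dataset whose third batch carries only two of four types.
sparse_partial_data <- function(seed) {
  cached(paste0("sparse_data_", seed), {
    pres <- list(batch1 = c("alpha", "beta", "gamma", "delta"),
                 batch2 = c("alpha", "beta", "gamma", "delta"),
                 batch3 = c("alpha", "beta"))
    m <- simulate_counts(simulation_config(scenario = "partial",
                                           type_presence = pres,
                                           seed = seed))
    preprocess(m, pipeline_config(min_genes_per_cell = 10, n_hvg = 300,
                                  random_seed = seed))
  })
}

# Naive autoencoder ablation: sparse custom anchor, unconstrained types
# transformed anyway, reconstruction loss only.
sparse_naive_ae_run <- function(seed) {
  cached(paste0("sparse_ae_", seed), {
    prep <- sparse_partial_data(seed)
    a <- select_anchor_custom(prep$matrix, "batch3", 1000, seed)
    map <- build_training_mapping(prep$matrix, a, prep$graph, seed,
                                  missing_type = "transform")
    fit <- train_aae(prep$matrix, map, a,
                     aae_config(ncol(prep$matrix$values), 32, epochs = 30,
                                batch_size = 256, seed = seed,
                                mode = "ae_only"))
    corr <- apply_correction(fit, prep$matrix, map)
    list(prep = prep, corr = corr)
  })
}

# Standard full-mode run (balanced anchor) on the same partial dataset.
sparse_full_run <- function(seed) {
  cached(paste0("sparse_full_", seed), {
    prep <- sparse_partial_data(seed)
    a <- select_anchor_balanced(prep$matrix, prep$graph, 1000, seed)
    map <- build_training_mapping(prep$matrix, a, prep$graph, seed)
    fit <- train_aae(prep$matrix, map, a,
                     aae_config(ncol(prep$matrix$values), 32, epochs = 30,
                                batch_size = 256, seed = seed))
    corr <- apply_correction(fit, prep$matrix, map)
    list(prep = prep, mapping = map, corr = corr)
  })
}

# Small run_all configuration used by smoke/determinism tests.
small_run_config <- function(seed) {
  list(simulation = list(n_batches = 2, cell_types = c("a", "b", "c"),
                         cells_per_type_per_batch = 60, n_genes = 100,
                         seed = seed),
       pipeline = list(min_genes_per_cell = 5, min_cells_per_gene = 3,
                       n_hvg = 100, random_seed = seed),
       train = list(latent_dim = 8, epochs = 5, batch_size = 64,
                    seed = seed),
       evaluate = list(seed = seed))
}
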