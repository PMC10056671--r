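test_that("cell filter keeps exactly-at-threshold cells and matches a brute-force double pass", {
  # 5 cells expressing {700, 600, 599, 0, 601} genes out of 800
  n_expr <- c(700, 600, 599, 0, 601)
  vals <- t(sapply(n_expr, function(k) c(rep(1, k), rep(0, 800 - k))))
  m <- annotated_matrix(vals, paste0("c", 1:5), paste0("g", 1:800),
                        rep("b", 5), rep("t", 5))
  f <- filter_cells_genes(m, 600, 1)
  expect_identical(f$cell_ids, c("c1", "c2", "c5"))

  # random matrix vs an independently coded two-pass filter
  set.seed(20)
  vals <- matrix(rpois(200 * 100, 0.8), 200, 100)
  m <- annotated_matrix(vals, sprintf("c%03d", 1:200),
                        sprintf("g%03d", 1:100),
                        rep(c("A", "B"), 100), rep(c("x", "y"), each = 100))
  f <- filter_cells_genes(m, 15, 5)
  keep_cells <- which(rowSums(vals > 0) >= 15)
  keep_genes <- which(colSums(vals[keep_cells, ] > 0) >= 5)
  expect_identical(f$cell_ids, m$cell_ids[keep_cells])
  expect_identical(f$gene_ids, m$gene_ids[keep_genes])
  expect_equal(unname(f$values), unname(vals[keep_cells, keep_genes]),
               ignore_attr = TRUE)

  # monotonicity: raising the threshold never adds cells
  f2 <- filter_cells_genes(m, 20, 5)
  expect_true(all(f2$cell_ids %in% f$cell_ids))

  expect_error(filter_cells_genes(m, 1e6, 1), "all cells removed")
})

test_that("highly variable gene selection finds planted variable genes", {
  # constant vs variable, n_hvg = 1
  vals <- cbind(rep(5, 30), c(rep(1, 15), rep(40, 15)))
  m <- annotated_matrix(vals, paste0("c", 1:30), c("flat", "var"),
                        rep("b", 30), rep("t", 30))
  expect_identical(select_hvg(m, 1)$gene_ids, "var")
  expect_identical(select_hvg(m, 2)$gene_ids, c("flat", "var"))
  expect_error(select_hvg(m, 3), "exceeds the number of genes")

  # 20 planted overdispersed genes among 200: the Poisson background spans a
  # range of mean expression levels (so the mean-dispersion trend is
  # supported everywhere) and the planted genes carry a lognormal rate
  # mixture that inflates variance several-fold at an ordinary mean
  set.seed(8)
  n <- 300
  lam <- runif(200, 5, 60)
  base <- matrix(rpois(n * 200, rep(lam, each = n)), n, 200)
  idx <- sample(200, 20)
  base[, idx] <- matrix(rpois(n * 20, 20 * rlnorm(n * 20, -0.5, 1)), n, 20)
  m <- annotated_matrix(base, sprintf("c%03d", 1:n), sprintf("g%03d", 1:200),
                        rep("b", n), rep("t", n))
  top20 <- select_hvg(m, 20)$gene_ids
  expect_gte(length(intersect(top20, m$gene_ids[idx])), 18)
})

test_that("total-count normalisation scales rows exactly and is idempotent", {
  m <- annotated_matrix(rbind(c(1, 1, 2)), "c1", c("g1", "g2", "g3"),
                        "b", "t")
  nm <- normalize_total(m, 20000)
  expect_equal(unname(nm$values[1, ]), c(5000, 5000, 10000))
  expect_identical(nm$layer_tag, "normalized")

  m <- random_annotated(30, 15, density = 0.8, seed = 4)
  nm <- normalize_total(m, 20000)
  expect_true(all(abs(rowSums(nm$values) - 20000) < 1e-2))
  nm2 <- normalize_total(nm, 20000)
  expect_equal(nm2$values, nm$values, tolerance = 1e-12)

  z <- annotated_matrix(rbind(c(0, 0), c(1, 1)), c("c1", "c2"),
                        c("g1", "g2"), c("b", "b"), c("t", "t"))
  expect_error(normalize_total(z), "zero total count")
})

test_that("log1p transform has the right closed forms and monotonicity", {
  m <- annotated_matrix(rbind(c(0, exp(1) - 1, 5)), "c1",
                        c("g1", "g2", "g3"), "b", "t")
  lt <- log1p_transform(m)
  expect_identical(lt$values[1, 1], 0)
  expect_equal(lt$values[1, 2], 1)
  expect_identical(lt$layer_tag, "lognormalized")

  set.seed(5)
  a <- runif(100, 0, 50); b <- a + runif(100, 0.01, 10)
  expect_true(all(log1p(a) < log1p(b)))
})

test_that("PCA matches an SVD oracle and handles degenerate shapes", {
  # rank-1 data: one nonzero variance component
  set.seed(41)
  u <- rnorm(40); v <- abs(rnorm(6))
  m1 <- annotated_matrix(abs(outer(u, v)), sprintf("c%02d", 1:40),
                         paste0("g", 1:6), rep("b", 40), rep("t", 40),
                         layer_tag = "lognormalized")
  p1 <- compute_pca(m1, 3)
  expect_gt(p1$explained_variance[1], 1e-8)
  expect_lt(p1$explained_variance[2] / p1$explained_variance[1], 1e-10)

  # 2D points on the line y = 2x: first direction prop to (1,2)/sqrt(5)
  x <- seq(0, 5, length.out = 25)
  m2 <- annotated_matrix(cbind(x, 2 * x), sprintf("c%02d", 1:25),
                         c("g1", "g2"), rep("b", 25), rep("t", 25),
                         layer_tag = "lognormalized")
  p2 <- compute_pca(m2, 1)
  dir <- p2$components[1, ]
  expect_equal(abs(dir), c(1, 2) / sqrt(5), tolerance = 1e-8)

  # random matrix vs direct SVD of the centred data
  set.seed(77)
  x <- matrix(rnorm(100 * 50), 100, 50)
  m3 <- annotated_matrix(abs(x), sprintf("c%03d", 1:100),
                         sprintf("g%02d", 1:50), rep("b", 100),
                         rep("t", 100), layer_tag = "lognormalized")
  p3 <- compute_pca(m3, 10)
  xc <- scale(m3$values, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  emb_oracle <- sv$u[, 1:10] %*% diag(sv$d[1:10])
  for (j in 1:10) {
    s <- sign(sum(emb_oracle[, j] * p3$embedding[, j]))
    expect_equal(p3$embedding[, j], s * emb_oracle[, j], tolerance = 1e-5)
  }
  # orthonormal loadings, non-increasing variance
  expect_equal(p3$components %*% t(p3$components), diag(10),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diff(p3$explained_variance) <= 1e-10))
  expect_error(compute_pca(m3, 60), "exceeds")
})

test_that("cross-batch graph equals the brute-force mutual-kNN oracle", {
  set.seed(30)
  n <- 60
  emb <- matrix(rnorm(n * 2), n, 2)
  batch <- rep(c("A", "B"), each = 30)
  type <- rep(rep(c("t1", "t2", "t3"), each = 10), 2)
  for (k in c(1, 3)) {
    g <- build_cross_batch_graph(emb, batch, type, k)
    oracle <- mutual_knn_oracle(emb, batch, type, k)
    got <- unique(g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE])
    expect_equal(unname(got), unname(unique(oracle)))
    # bipartite across batches, same type
    expect_true(all(batch[g$edges[, 1]] != batch[g$edges[, 2]]))
    expect_true(all(type[g$edges[, 1]] == type[g$edges[, 2]]))
  }

  # saturation: k = all candidates -> complete bipartite graph per type
  emb2 <- matrix(rnorm(12 * 2), 12, 2)
  b2 <- rep(c("A", "B"), each = 6)
  t2 <- rep("t", 12)
  suppressWarnings(g2 <- build_cross_batch_graph(emb2, b2, t2, 6))
  expect_identical(nrow(g2$edges), 36L)

  # a type present in only one batch contributes no edges
  t3 <- c(rep("t", 6), rep("solo", 6))
  b3 <- rep(c("A", "B"), each = 6)
  suppressWarnings(g3 <- build_cross_batch_graph(emb2, b3, t3, 2))
  expect_identical(nrow(g3$edges), 0L)
})

test_that("the preprocessing chain runs in the published order", {
  m <- simulate_counts(simulation_config(n_batches = 2,
                                         cell_types = c("a", "b"),
                                         cells_per_type_per_batch = 40,
                                         n_genes = 120, seed = 2))
  prep <- preprocess(m, pipeline_config(min_genes_per_cell = 5,
                                        min_cells_per_gene = 3,
                                        n_hvg = 80, random_seed = 2))
  expect_identical(prep$matrix$layer_tag, "lognormalized")
  expect_identical(ncol(prep$matrix$values), 80L)
  # row sums of expm1 differ from target because log1p follows normalize;
  # instead check that the pre-log values summed to the target
  expect_true(all(abs(rowSums(expm1(prep$matrix$values)) - 20000) < 1e-6))
  expect_s3_class(prep$pca, "PCAResult")
  expect_s3_class(prep$graph, "ConnectivityGraph")
})
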