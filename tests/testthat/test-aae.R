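# small trained-free parameter set for encode/decode contract tests
fresh_params <- function(n_genes = 12, latent = 4, seed = 3) {
  set.seed(seed)
  imaae:::init_aae_params(aae_config(n_genes, latent,
                                     encoder_widths = c(n_genes, 8, latent),
                                     decoder_widths = c(latent, 8, n_genes),
                                     critic_widths = c(latent, 6, 1)))
}

test_that("encoding reparameterises deterministically with the right noise scale", {
  p <- fresh_params()
  x <- matrix(abs(rnorm(30 * 12)), 30, 12)
  set.seed(10); e1 <- aae_encode(p, x, sample = TRUE)
  set.seed(10); e2 <- aae_encode(p, x, sample = TRUE)
  expect_identical(e1$z, e2$z)
  expect_equal(e1$z, e1$mu + exp(e1$logvar / 2) * (e1$z - e1$mu))

  # with eps = 0, z == mu
  e0 <- aae_encode(p, x, sample = FALSE)
  expect_identical(e0$z, e0$mu)

  # Monte-Carlo: sd of z - mu matches exp(logvar/2) within 5%
  x1 <- x[1, , drop = FALSE]
  set.seed(11)
  draws <- replicate(10000, {
    e <- aae_encode(p, x1, sample = TRUE)
    e$z[1, ]
  })
  e <- aae_encode(p, x1, sample = FALSE)
  sds <- apply(draws, 1, sd)
  expect_true(all(abs(sds / exp(e$logvar[1, ] / 2) - 1) < 0.05))

  # logvar is clamped
  expect_true(all(e$logvar >= -20 & e$logvar <= 5))
  expect_error(aae_encode(p, x[, 1:5]), "does not match encoder input")
})

test_that("decoding is non-negative with the expected width", {
  p <- fresh_params(seed = 4)
  z <- matrix(rnorm(50 * 4, sd = 5), 50, 4)
  out <- aae_decode(p, z)
  expect_true(min(out) >= 0)
  expect_identical(ncol(out), 12L)

  pz <- p
  pz$decoder <- lapply(pz$decoder, function(l)
    list(W = l$W * 0, b = l$b * 0))
  expect_true(all(aae_decode(pz, z) == 0))
  expect_error(aae_decode(p, z[, 1:2]), "does not match decoder input")
})

test_that("reconstruction loss matches hand arithmetic", {
  expect_identical(reconstruction_loss(rbind(c(1, 0)), rbind(c(1, 0))), 0)
  expect_identical(reconstruction_loss(rbind(c(1, 0)), rbind(c(0, 0))), 1)
  expect_identical(
    reconstruction_loss(rbind(c(1, 2), c(3, 4)), rbind(c(0, 0), c(0, 0))),
    15)
  expect_error(reconstruction_loss(rbind(c(1, 2)), rbind(1)),
               "shape mismatch")
})

test_that("gradient penalty has the closed-form corner cases", {
  # linear critic with unit gradient: penalty 0 everywhere
  w <- c(3, 4) / 5
  critic_unit <- list(list(W = matrix(w, 1), b = 0))
  set.seed(2)
  zr <- matrix(rnorm(40), 20); zf <- matrix(rnorm(40), 20)
  expect_equal(gradient_penalty(critic_unit, zr, zf, 10), 0)

  # constant critic: zero gradient -> penalty lambda
  critic_const <- list(list(W = matrix(0, 1, 2), b = 7))
  expect_equal(gradient_penalty(critic_const, zr, zf, 10), 10)
  expect_equal(gradient_penalty(critic_const, zr, zf, 2.5), 2.5)
  expect_error(gradient_penalty(critic_const, zr, zf, -1), "non-negative")
})

test_that("gradient penalty matches finite differences on a tiny critic", {
  set.seed(14)
  critic <- imaae:::mlp_init(c(3, 2, 1))
  z <- matrix(rnorm(15), 5, 3)
  # value: FD gradient norm per row
  lambda <- 10
  h <- 1e-5
  pen_fd <- sapply(1:5, function(i) {
    g <- sapply(1:3, function(j) {
      zp <- z; zp[i, j] <- zp[i, j] + h
      zm <- z; zm[i, j] <- zm[i, j] - h
      (imaae:::mlp_forward(critic, zp)$out[i] -
         imaae:::mlp_forward(critic, zm)$out[i]) / (2 * h)
    })
    (sqrt(sum(g^2)) - 1)^2
  })
  got <- imaae:::gp_at(critic, z, lambda)$value
  expect_equal(got, lambda * mean(pen_fd), tolerance = 1e-4)

  # parameter gradients of the penalty: FD on every weight
  gp <- imaae:::gp_at(critic, z, lambda, with_grads = TRUE)
  for (l in 1:2) for (i in seq_along(critic[[l]]$W)) {
    cp <- critic; cp[[l]]$W[i] <- cp[[l]]$W[i] + h
    cm <- critic; cm[[l]]$W[i] <- cm[[l]]$W[i] - h
    fd <- (imaae:::gp_at(cp, z, lambda)$value -
             imaae:::gp_at(cm, z, lambda)$value) / (2 * h)
    expect_equal(gp$grads[[l]]$W[i], fd, tolerance = 1e-4)
  }
})

test_that("critic and generator losses satisfy their algebraic identities", {
  set.seed(3)
  zr <- matrix(rnorm(60), 30); zf <- matrix(rnorm(60), 30)

  # constant critic: value terms cancel, only the penalty remains
  critic_const <- list(list(W = matrix(0, 1, 2), b = 4))
  expect_equal(critic_loss(critic_const, zr, zf, 10), 10)
  expect_equal(generator_loss(critic_const, zf), -4)

  # identical real and fake batches: value terms cancel exactly
  critic <- imaae:::mlp_init(c(2, 5, 1))
  set.seed(4)
  l <- critic_loss(critic, zr, zr, 0)
  expect_equal(l, 0, tolerance = 1e-12)

  # L_G == -(fake term of L_D without penalty)
  expect_equal(generator_loss(critic, zf),
               -(mean(imaae:::mlp_forward(critic, zf)$out)))

  # law of large numbers: D(z) = w.z with |w| = 1, fakes mean-shifted by m
  w <- c(1, 0)
  critic_lin <- list(list(W = matrix(w, 1), b = 0))
  set.seed(5)
  n <- 1e5
  zr <- matrix(rnorm(2 * n), n)
  m_shift <- c(1.5, 0)
  zf <- matrix(rnorm(2 * n), n) + rep(m_shift, each = n)
  ld <- critic_loss(critic_lin, zr, zf, 10)   # unit gradient -> penalty 0
  se <- sqrt(2 / n)
  expect_lt(abs(ld - sum(w * m_shift)), 3 * se)
})

test_that("a generator step increases the critic score of fakes", {
  set.seed(8)
  critic <- imaae:::mlp_init(c(3, 4, 1))
  p <- fresh_params(n_genes = 6, latent = 3, seed = 9)
  x <- matrix(abs(rnorm(40 * 6)), 40, 6)
  set.seed(1); ef <- imaae:::encoder_forward(p$encoder, x, sample = TRUE)
  before <- mean(imaae:::mlp_forward(critic, ef$z)$out)
  cc <- imaae:::mlp_forward(critic, ef$z)
  dz <- -imaae:::mlp_input_grad(critic, cc) / nrow(x)
  grads <- imaae:::encoder_backward(p$encoder, ef, dz)
  layers <- c(p$encoder$trunk, list(p$encoder$mu, p$encoder$logvar))
  st <- imaae:::adam_init(layers)
  up <- imaae:::adam_step(layers, grads, st, 1, 0.05)
  enc2 <- p$encoder
  nt <- length(enc2$trunk)
  if (nt) enc2$trunk <- up$layers[seq_len(nt)]
  enc2$mu <- up$layers[[nt + 1]]; enc2$logvar <- up$layers[[nt + 2]]
  set.seed(1); ef2 <- imaae:::encoder_forward(enc2, x, sample = TRUE)
  after <- mean(imaae:::mlp_forward(critic, ef2$z)$out)
  expect_gt(after, before)
})

test_that("training runs, records finite history, and is reproducible", {
  set.seed(60)
  vals <- matrix(abs(rnorm(50 * 20, 2, 1)), 50, 20)
  m <- annotated_matrix(vals, sprintf("c%02d", 1:50), paste0("g", 1:20),
                        rep(c("A", "B"), 25), rep(c("t1", "t2"), each = 25),
                        layer_tag = "lognormalized")
  a <- select_anchor_balanced(m, NULL, 1000, 1)
  map <- build_training_mapping(m, a, NULL, 1)
  cfg <- aae_config(20, 8, encoder_widths = c(20, 12, 8),
                    decoder_widths = c(8, 12, 20),
                    critic_widths = c(8, 6, 1),
                    epochs = 1, batch_size = 64, seed = 0)
  fit <- suppressWarnings(train_aae(m, map, a, cfg))
  expect_identical(nrow(fit$history), 1L)
  expect_true(all(is.finite(unlist(fit$history))))

  cfg$epochs <- 3L
  f1 <- suppressWarnings(train_aae(m, map, a, cfg))
  f2 <- suppressWarnings(train_aae(m, map, a, cfg))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$decoder, f2$decoder)

  # recorded L_G equals -mean critic score of the saved fake batch
  expect_equal(f1$last_step$L_G,
               -mean(imaae:::mlp_forward(f1$critic,
                                         f1$last_step$z_fake)$out))
})

test_that("reconstruction loss falls by at least half during training", {
  drops <- 0
  for (seed in 1:3) {
    # strong type programs so the anchor targets have structure a constant
    # predictor cannot capture
    m <- simulate_counts(simulation_config(n_batches = 2,
                                           cell_types = c("a", "b"),
                                           cells_per_type_per_batch = 50,
                                           n_genes = 80, de_logfc = 2,
                                           de_fraction = 0.3, seed = seed))
    prep <- preprocess(m, pipeline_config(min_genes_per_cell = 5,
                                          n_hvg = 80, random_seed = seed))
    a <- select_anchor_balanced(prep$matrix, prep$graph, 1000, seed)
    map <- build_training_mapping(prep$matrix, a, prep$graph, seed)
    fit <- train_aae(prep$matrix, map, a,
                     aae_config(ncol(prep$matrix$values), 8, epochs = 30,
                                batch_size = 64, seed = seed))
    h <- fit$history$L_R
    if (h[length(h)] <= 0.5 * h[1]) drops <- drops + 1
  }
  expect_gte(drops, 2)
})

test_that("adversarial-only updates pull an offset latent towards the prior", {
  # encoder = identity mu head on 2-D inputs centred at (5, 5); the critic
  # against N(0, I) must drag the code towards the origin
  set.seed(3)
  X <- matrix(rnorm(400 * 2, mean = 5, sd = 2), 400)
  cfg <- list(gp_weight = 10, learning_rate = 2e-3, adam_beta1 = 0.5,
              adam_beta2 = 0.999)
  enc <- list(trunk = list(), mu = list(W = diag(2), b = c(0, 0)),
              logvar = list(W = matrix(0, 2, 2), b = c(-4, -4)))
  critic <- imaae:::mlp_init(c(2, 16, 8, 1))
  cr_state <- imaae:::adam_init(critic)
  gen_state <- imaae:::adam_init(list(enc$mu, enc$logvar))
  start_norm <- sqrt(sum(colMeans(
    imaae:::encoder_forward(enc, X, TRUE)$z)^2))
  for (step in 1:800) {
    idx <- sample(400, 128)
    xb <- X[idx, ]
    zf <- imaae:::encoder_forward(enc, xb, TRUE)$z
    zr <- matrix(rnorm(128 * 2), 128)
    cu <- imaae:::critic_update(critic, cr_state, step, zr, zf, cfg)
    critic <- cu$critic; cr_state <- cu$state
    ef <- imaae:::encoder_forward(enc, xb, TRUE)
    cc <- imaae:::mlp_forward(critic, ef$z)
    dz <- -imaae:::mlp_input_grad(critic, cc) / 128
    up <- imaae:::adam_step(list(enc$mu, enc$logvar),
                            imaae:::encoder_backward(enc, ef, dz),
                            gen_state, step, cfg$learning_rate)
    gen_state <- up$state
    enc$mu <- up$layers[[1]]; enc$logvar <- up$layers[[2]]
  }
  z <- imaae:::encoder_forward(enc, X, TRUE)$z
  end_norm <- sqrt(sum(colMeans(z)^2))
  expect_lt(end_norm, 0.25 * start_norm)
  expect_true(all(apply(z, 2, var) < 10))
})
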