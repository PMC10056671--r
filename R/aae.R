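#' Adversarial autoencoder configuration
#'
#' The model has three parts: an encoder ending in a reparameterised Gaussian
#' latent code, a decoder whose terminal ReLU guarantees non-negative
#' expression output, and a Wasserstein critic with gradient penalty that
#' pushes the latent distribution towards the standard Gaussian prior
#' N(0, I).
#'
#' Default layer widths follow the published architecture for 2000 input
#' genes — encoder 2000/1000/500/250, decoder mirrored, critic
#' 250/125/64/8/1 — and scale geometrically between `n_genes` and
#' `latent_dim` for other input sizes.
#'
#' @param n_genes Number of input genes (first encoder width).
#' @param latent_dim Latent code dimension (last encoder width).
#' @param encoder_widths,decoder_widths,critic_widths Optional explicit layer
#'   widths (including input and output sizes).
#' @param learning_rate,adam_beta1,adam_beta2 Adam optimiser settings.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param n_critic Critic updates per autoencoder update; defaults to the
#'   number of batches in the training data when left `NULL`.
#' @param gp_weight Weight of the gradient-penalty term (lambda).
#' @param seed Integer seed; training is fully deterministic given it.
#' @param mode `"full"` (reconstruction + adversarial latent matching),
#'   `"ae_only"` (reconstruction only) or `"gan_only"` (decoder trained as a
#'   generator against an expression-space critic, no reconstruction loss) —
#'   the last two are ablations.
#' @return An `AAEConfig` list.
#' @export
aae_config <- function(n_genes, latent_dim = 250,
                       encoder_widths = NULL, decoder_widths = NULL,
                       critic_widths = NULL,
                       learning_rate = 2e-4, adam_beta1 = 0.5,
                       adam_beta2 = 0.999, batch_size = 1024, epochs = 100,
                       n_critic = NULL, gp_weight = 10, seed = 1L,
                       mode = c("full", "ae_only", "gan_only")) {
  mode <- match.arg(mode)
  if (is.null(encoder_widths))
    encoder_widths <- geom_widths(n_genes, latent_dim, 4L)
  if (is.null(decoder_widths)) decoder_widths <- rev(encoder_widths)
  if (is.null(critic_widths))
    critic_widths <- if (latent_dim == 250) c(250, 125, 64, 8, 1) else
      c(latent_dim, max(8, round(latent_dim / 2)),
        max(8, round(latent_dim / 4)), 8, 1)
  stopifnot(encoder_widths[1] == n_genes,
            utils::tail(decoder_widths, 1) == n_genes,
            utils::tail(encoder_widths, 1) == latent_dim,
            decoder_widths[1] == latent_dim,
            critic_widths[1] == latent_dim,
            utils::tail(critic_widths, 1) == 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            gp_weight >= 0,
            is.null(n_critic) || n_critic >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 critic_widths = as.integer(critic_widths),
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_critic = if (is.null(n_critic)) NULL else
                   as.integer(n_critic),
                 gp_weight = gp_weight, seed = as.integer(seed),
                 mode = mode),
            class = "AAEConfig")
}

# 4-point geometric ladder between two widths; reproduces 2000/1000/500/250.
geom_widths <- function(from, to, n = 4L)
  unique(round(exp(seq(log(from), log(to), length.out = n))))

logvar_clamp <- c(-20, 5)

# Internal: fresh parameter containers for one model (uses the current RNG).
init_aae_params <- function(config, critic_in = config$latent_dim) {
  ew <- config$encoder_widths
  k <- length(ew)
  trunk <- if (k > 2) mlp_init(ew[seq_len(k - 1L)]) else list()
  head_in <- ew[k - 1L]
  mu_head <- mlp_init(c(head_in, config$latent_dim))[[1L]]
  # small mu head: the latent code starts near the N(0, I) prior instead of
  # far outside it, where the critic's gentle gradients would need many more
  # steps to pull it back
  mu_head$W <- mu_head$W * 0.1
  mu_head$b <- mu_head$b * 0
  encoder <- list(
    trunk = trunk,
    mu = mu_head,
    # zero-initialised so the initial posterior sd is 1; a randomly
    # initialised logvar head injects latent noise with sd up to e^2 that
    # the decoder can never remove
    logvar = list(W = matrix(0, config$latent_dim, head_in),
                  b = numeric(config$latent_dim)))
  decoder <- mlp_init(config$decoder_widths)
  cw <- config$critic_widths
  cw[1L] <- critic_in
  critic <- mlp_init(cw)
  list(encoder = encoder, decoder = decoder, critic = critic)
}

# Internal: encoder forward pass with caches.
encoder_forward <- function(encoder, x, sample = TRUE) {
  tc <- if (length(encoder$trunk))
    mlp_forward(encoder$trunk, x, final = "relu") else
      list(h = list(x), a = list(), out = x, final = "relu")
  H <- tc$out
  mu <- sweep(H %*% t(encoder$mu$W), 2L, encoder$mu$b, "+")
  lv_raw <- sweep(H %*% t(encoder$logvar$W), 2L, encoder$logvar$b, "+")
  lv <- pmin(pmax(lv_raw, logvar_clamp[1]), logvar_clamp[2])
  eps <- if (sample)
    matrix(stats::rnorm(length(mu)), nrow = nrow(mu)) else mu * 0
  z <- mu + exp(lv / 2) * eps
  list(trunk_cache = tc, H = H, mu = mu, logvar = lv, lv_raw = lv_raw,
       eps = eps, z = z)
}

# Internal: gradients of a loss w.r.t. the encoder parameters given dLoss/dz
# at a cached forward pass. Returns list(trunk grads ..., mu grads, logvar
# grads) matching the c(trunk, mu, logvar) layer order. The logvar path
# gets no gradient where the clamp is active.
encoder_backward <- function(enc, ef, dz) {
  clamp_ok <- (ef$lv_raw > logvar_clamp[1]) & (ef$lv_raw < logvar_clamp[2])
  dmu <- dz
  dlv <- dz * ef$eps * exp(ef$logvar / 2) * 0.5 * clamp_ok
  g_mu <- list(W = t(dmu) %*% ef$H, b = colSums(dmu))
  g_lv <- list(W = t(dlv) %*% ef$H, b = colSums(dlv))
  dH <- dmu %*% enc$mu$W + dlv %*% enc$logvar$W
  trunk_grads <- if (length(enc$trunk))
    mlp_backward(enc$trunk, ef$trunk_cache, dH)$grads else list()
  c(trunk_grads, list(g_mu, g_lv))
}

#' Encode expression rows into the latent space
#'
#' Applies the encoder and the reparameterisation step
#' `z = mu + exp(logvar/2) * eps` with `eps ~ N(0, I)` drawn from R's RNG
#' (deterministic under `set.seed()`). `logvar` is clamped to \[-20, 5\] for
#' numerical safety; with `sample = FALSE`, `eps = 0` and `z = mu`.
#'
#' @param model A `TrainedAAE` (or a raw parameter list with an `encoder`).
#' @param x Matrix of log-normalised expression rows (cells x genes).
#' @param sample Draw the stochastic latent (`TRUE`) or return the mean code.
#' @return List with `mu`, `logvar`, `z` (all cells x latent_dim).
#' @export
aae_encode <- function(model, x, sample = TRUE) {
  enc <- model$encoder
  x <- as.matrix(x)
  in_dim <- if (length(enc$trunk)) ncol(enc$trunk[[1]]$W) else
    ncol(enc$mu$W)
  if (ncol(x) != in_dim)
    stop("input width ", ncol(x), " does not match encoder input width ",
         in_dim)
  f <- encoder_forward(enc, x, sample = sample)
  list(mu = f$mu, logvar = f$logvar, z = f$z)
}

#' Decode latent codes into expression rows
#'
#' The decoder's terminal activation is a ReLU, so every output entry is
#' non-negative by construction.
#'
#' @param model A `TrainedAAE` (or raw parameter list with a `decoder`).
#' @param z Matrix of latent codes (cells x latent_dim).
#' @return Matrix of non-negative expression rows (cells x genes).
#' @export
aae_decode <- function(model, z) {
  z <- as.matrix(z)
  dec <- model$decoder
  if (ncol(z) != ncol(dec[[1]]$W))
    stop("latent width ", ncol(z), " does not match decoder input width ",
         ncol(dec[[1]]$W))
  mlp_forward(dec, z, final = "relu")$out
}

#' Autoencoder reconstruction loss
#'
#' Mean over cells of the squared Euclidean distance between target and
#' generated expression rows.
#'
#' @param x Target rows (for training, the mapped anchor profiles).
#' @param x_hat Generated rows.
#' @return Non-negative scalar; zero iff `x == x_hat`.
#' @export
reconstruction_loss <- function(x, x_hat) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat)))
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x_hat), collapse = "x"))
  mean(rowSums((x - x_hat)^2))
}

# Internal: penalty value and critic gradients at given interpolates.
# Double backprop specialised to ReLU networks: with activation masks held
# fixed (their derivative vanishes almost everywhere), the input gradient is
# multilinear in the weights, so d/dW of (|grad| - 1)^2 reduces to a second
# forward/backward sweep. Bias gradients of the penalty term are zero a.e.
gp_at <- function(critic, z_hat, lambda, with_grads = FALSE) {
  n <- nrow(z_hat)
  cache <- mlp_forward(critic, z_hat, final = "linear")
  g <- mlp_input_grad(critic, cache)
  r <- sqrt(rowSums(g^2))
  value <- lambda * mean((r - 1)^2)
  if (!with_grads) return(list(value = value))
  L <- length(critic)
  u <- g * ifelse(r > 0, 2 * (r - 1) / r, 0)
  grads <- grads_zero(critic)
  S <- vector("list", L)           # S[[l]] = masked chain state after layer l
  s_prev <- u
  for (l in seq_len(L - 1L)) {
    S[[l]] <- (s_prev %*% t(critic[[l]]$W)) * (cache$a[[l]] > 0)
    s_prev <- S[[l]]
  }
  s_in <- function(l) if (l == 1L) u else S[[l - 1L]]
  grads[[L]]$W <- (lambda / n) *
    matrix(colSums(s_in(L)), nrow = 1L)
  C <- matrix(critic[[L]]$W, nrow = n, ncol = ncol(critic[[L]]$W),
              byrow = TRUE)
  for (l in rev(seq_len(L - 1L))) {
    E <- C * (cache$a[[l]] > 0)
    grads[[l]]$W <- (lambda / n) * (t(E) %*% s_in(l))
    C <- E %*% critic[[l]]$W
  }
  list(value = value, grads = grads)
}

#' Gradient penalty of the Wasserstein critic
#'
#' Interpolates `z_hat = alpha * z_real + (1 - alpha) * z_fake` with per-row
#' `alpha ~ U(0, 1)` and returns
#' `lambda * mean((||grad_z D(z_hat)|| - 1)^2)`, the penalty that drives the
#' critic's gradient norm towards 1.
#'
#' @param critic Critic parameter list (layers of `W`, `b`).
#' @param z_real Rows sampled from the prior N(0, I).
#' @param z_fake Encoder outputs (same number of rows).
#' @param lambda Non-negative penalty weight.
#' @return Non-negative scalar.
#' @export
gradient_penalty <- function(critic, z_real, z_fake, lambda = 10) {
  z_real <- as.matrix(z_real); z_fake <- as.matrix(z_fake)
  if (lambda < 0) stop("lambda must be non-negative")
  if (nrow(z_real) != nrow(z_fake))
    stop("z_real and z_fake must have equal row counts")
  alpha <- stats::runif(nrow(z_real))
  z_hat <- alpha * z_real + (1 - alpha) * z_fake
  gp_at(critic, z_hat, lambda)$value
}

#' Critic (discriminator) loss
#'
#' Wasserstein critic loss with gradient penalty:
#' `-mean(D(z_real)) + mean(D(z_fake)) + gradient_penalty(...)`. Real
#' samples come from the Gaussian prior, fakes from the encoder: driving the
#' critic apart on the two forces the encoder's latent distribution towards
#' the prior.
#'
#' @inheritParams gradient_penalty
#' @return Scalar loss.
#' @export
critic_loss <- function(critic, z_real, z_fake, lambda = 10) {
  z_real <- as.matrix(z_real); z_fake <- as.matrix(z_fake)
  if (ncol(z_real) != ncol(z_fake) || nrow(z_real) != nrow(z_fake))
    stop("z_real / z_fake shape mismatch")
  -mean(mlp_forward(critic, z_real)$out) +
    mean(mlp_forward(critic, z_fake)$out) +
    gradient_penalty(critic, z_real, z_fake, lambda)
}

#' Generator loss
#'
#' `-mean(D(z_fake))`: the encoder (as generator) is rewarded when the
#' critic scores its latent codes like prior samples.
#'
#' @param critic Critic parameter list.
#' @param z_fake Encoder outputs.
#' @return Scalar loss.
#' @export
generator_loss <- function(critic, z_fake) {
  -mean(mlp_forward(critic, as.matrix(z_fake))$out)
}

# Internal: one critic Adam update; returns new critic/state and the loss.
critic_update <- function(critic, state, t, z_real, z_fake, cfg) {
  n <- nrow(z_real)
  cache_r <- mlp_forward(critic, z_real)
  cache_f <- mlp_forward(critic, z_fake)
  gr <- mlp_backward(critic, cache_r,
                     matrix(-1 / n, n, 1))$grads
  gf <- mlp_backward(critic, cache_f, matrix(1 / n, n, 1))$grads
  alpha <- stats::runif(n)
  z_hat <- alpha * z_real + (1 - alpha) * z_fake
  gp <- gp_at(critic, z_hat, cfg$gp_weight, with_grads = TRUE)
  loss <- -mean(cache_r$out) + mean(cache_f$out) + gp$value
  grads <- grads_add(grads_add(gr, gf), gp$grads)
  up <- adam_step(critic, grads, state, t, cfg$learning_rate,
                  cfg$adam_beta1, cfg$adam_beta2)
  list(critic = up$layers, state = up$state, loss = loss)
}

#' Train the adversarial autoencoder
#'
#' Per minibatch of (source cell, anchor target) pairs the critic is updated
#' `n_critic` times (real = prior draws, fake = fresh encoder outputs), then
#' the autoencoder takes one Adam step minimising the reconstruction loss of
#' the decoder output against the *mapped anchor target* plus the generator
#' loss on the encoder. Only non-passthrough, mapped cells enter training;
#' uniform (non-graph-linked) pairings are resampled every epoch. Training
#' draws only from R's RNG and is deterministic under the config seed.
#'
#' Ablation modes: `ae_only` drops the critic and generator terms entirely;
#' `gan_only` drops the reconstruction term and instead trains
#' encoder+decoder as a generator against a critic on expression space
#' (real = anchor profiles, fake = decoder outputs).
#'
#' @param m Log-normalised `AnnotatedMatrix` (the preprocessed data).
#' @param mapping A [build_training_mapping()] result for `m`.
#' @param anchors The `AnchorSet` the mapping points into.
#' @param config An [aae_config()]; its `n_genes` must equal `ncol(m$values)`.
#' @return A `TrainedAAE`: parameter containers (`encoder`, `decoder`,
#'   `critic`), per-epoch `history` (`L_R`, `L_D`, `L_G`), the resolved
#'   `config`, `gene_ids`, and `last_step` diagnostics.
#' @export
train_aae <- function(m, mapping, anchors, config) {
  stopifnot(inherits(m, "AnnotatedMatrix"), inherits(config, "AAEConfig"))
  if (m$layer_tag != "lognormalized")
    warning("training data layer_tag is '", m$layer_tag,
            "'; the model expects log-normalised input")
  if (config$n_genes != ncol(m$values))
    stop("config n_genes (", config$n_genes,
         ") does not match data gene count (", ncol(m$values), ")")
  pairs <- mapping$pairs
  if (!nrow(pairs)) stop("no trainable cells: all cells are passthrough")
  n_train <- nrow(pairs)
  cfg <- config
  if (is.null(cfg$n_critic)) cfg$n_critic <- max(1L, nlevels(m$batch))
  if (cfg$batch_size > n_train) {
    warning("batch_size (", cfg$batch_size, ") exceeds trainable cells (",
            n_train, "); using full batch")
    cfg$batch_size <- n_train
  }
  set.seed(cfg$seed)
  params <- init_aae_params(cfg, critic_in =
    if (cfg$mode == "gan_only") cfg$n_genes else cfg$latent_dim)
  enc <- params$encoder; dec <- params$decoder; critic <- params$critic
  # Terminal decoder layer starts at the mean anchor profile with shrunk
  # weights: the output begins near the target centre with every ReLU unit
  # alive, and the network learns residuals. Zero-centred initialisation
  # instead leaves a substantial fraction of terminal units permanently dead
  # (pre-activation negative for every input), pinning those genes to 0.
  dL <- length(dec)
  dec[[dL]]$b <- colMeans(anchors$anchor_profiles)
  dec[[dL]]$W <- dec[[dL]]$W * 0.1
  ae_layers <- c(enc$trunk, list(enc$mu, enc$logvar), dec)
  ae_state <- adam_init(ae_layers)
  cr_state <- adam_init(critic)
  n_trunk <- length(enc$trunk)
  ae_t <- 0L; cr_t <- 0L
  hist <- matrix(NA_real_, cfg$epochs, 3,
                 dimnames = list(NULL, c("L_R", "L_D", "L_G")))
  last_step <- NULL
  X <- m$values
  A <- anchors$anchor_profiles
  for (epoch in seq_len(cfg$epochs)) {
    pairs_e <- if (epoch > 1L && any(!mapping$fixed))
      resample_mapping_pairs(mapping) else pairs
    ord <- sample.int(n_train)
    starts <- seq(1L, n_train, by = cfg$batch_size)
    ep_losses <- matrix(0, length(starts), 3)
    for (s in seq_along(starts)) {
      idx <- ord[starts[s]:min(starts[s] + cfg$batch_size - 1L, n_train)]
      xb <- X[pairs_e[idx, 1L], , drop = FALSE]
      tb <- A[pairs_e[idx, 2L], , drop = FALSE]
      nb <- nrow(xb)
      l_d <- 0
      if (cfg$mode == "full") {
        for (ct in seq_len(cfg$n_critic)) {
          zf <- encoder_forward(enc, xb, sample = TRUE)$z
          zr <- matrix(stats::rnorm(nb * cfg$latent_dim), nb)
          cr_t <- cr_t + 1L
          cu <- critic_update(critic, cr_state, cr_t, zr, zf, cfg)
          critic <- cu$critic; cr_state <- cu$state; l_d <- cu$loss
        }
      } else if (cfg$mode == "gan_only") {
        for (ct in seq_len(cfg$n_critic)) {
          ef <- encoder_forward(enc, xb, sample = TRUE)
          xf <- mlp_forward(dec, ef$z, final = "relu")$out
          cr_t <- cr_t + 1L
          cu <- critic_update(critic, cr_state, cr_t, tb, xf, cfg)
          critic <- cu$critic; cr_state <- cu$state; l_d <- cu$loss
        }
      }
      # --- autoencoder + generator step: one Adam update of encoder and
      # decoder on the combined objective (L_R towards the mapped anchor
      # target, plus L_G through the critic) ---
      ef <- encoder_forward(enc, xb, sample = TRUE)
      dec_cache <- mlp_forward(dec, ef$z, final = "relu")
      x_hat <- dec_cache$out
      l_r <- mean(rowSums((tb - x_hat)^2))
      l_g <- 0
      d_xhat <- matrix(0, nb, ncol(x_hat))
      dz_extra <- matrix(0, nb, cfg$latent_dim)
      if (cfg$mode != "gan_only")
        d_xhat <- 2 * (x_hat - tb) / nb
      if (cfg$mode == "full") {
        ccache <- mlp_forward(critic, ef$z)
        l_g <- -mean(ccache$out)
        dz_extra <- -mlp_input_grad(critic, ccache) / nb
      } else if (cfg$mode == "gan_only") {
        # decoder-as-generator against an expression-space critic; no
        # reconstruction term
        ccache <- mlp_forward(critic, x_hat)
        l_g <- -mean(ccache$out)
        d_xhat <- d_xhat - mlp_input_grad(critic, ccache) / nb
      }
      dec_back <- mlp_backward(dec, dec_cache, d_xhat)
      enc_grads <- encoder_backward(enc, ef, dec_back$d_in + dz_extra)
      ae_t <- ae_t + 1L
      up <- adam_step(ae_layers, c(enc_grads, dec_back$grads), ae_state,
                      ae_t, cfg$learning_rate, cfg$adam_beta1,
                      cfg$adam_beta2)
      ae_layers <- up$layers; ae_state <- up$state
      if (n_trunk) enc$trunk <- ae_layers[seq_len(n_trunk)]
      enc$mu <- ae_layers[[n_trunk + 1L]]
      enc$logvar <- ae_layers[[n_trunk + 2L]]
      dec <- ae_layers[(n_trunk + 3L):length(ae_layers)]
      ep_losses[s, ] <- c(l_r, l_d, l_g)
      last_step <- list(z_fake = if (cfg$mode == "gan_only") x_hat else
                          ef$z, L_G = l_g)
    }
    hist[epoch, ] <- colMeans(ep_losses)
    if (!all(is.finite(hist[epoch, ])))
      stop("non-finite loss at epoch ", epoch,
           "; lower the learning rate or check the input scale")
  }
  structure(list(encoder = enc, decoder = dec, critic = critic,
                 config = cfg,
                 history = as.data.frame(cbind(epoch = seq_len(cfg$epochs),
                                               hist)),
                 gene_ids = m$gene_ids,
                 last_step = last_step),
            class = "TrainedAAE")
}

#' @export
print.TrainedAAE <- function(x, ...) {
  h <- x$history
  cat("TrainedAAE [", x$config$mode, "]: ", x$config$n_genes, " genes, ",
      "latent ", x$config$latent_dim, ", ", nrow(h), " epochs\n", sep = "")
  cat(sprintf("  final losses: L_R=%.4g L_D=%.4g L_G=%.4g\n",
              h$L_R[nrow(h)], h$L_D[nrow(h)], h$L_G[nrow(h)]))
  invisible(x)
}
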