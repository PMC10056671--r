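# Minimal fully-connected network primitives used by the adversarial
# autoencoder: He-initialised affine layers with ReLU hidden activations,
# reverse-mode gradients, and an Adam optimiser. Everything operates on
# row-major minibatches (rows = samples) and draws exclusively from R's RNG,
# so training is deterministic under set.seed().

# widths: layer sizes including input, e.g. c(300, 128, 64).
# Returns list of layers, each list(W = out x in, b = out).
# A small positive bias keeps ReLU units initially active; zero-bias He
# initialisation leaves a large fraction of units dead from the start
# (their pre-activation negative for every input), and a dead terminal
# decoder unit pins that gene's output to 0 permanently.
mlp_init <- function(widths, bias_init = 0.1) {
  lapply(seq_len(length(widths) - 1L), function(l) {
    fan_in <- widths[l]
    list(W = matrix(stats::rnorm(widths[l + 1L] * fan_in,
                                 sd = sqrt(2 / fan_in)),
                    nrow = widths[l + 1L]),
         b = rep(bias_init, widths[l + 1L]))
  })
}

# Forward pass. final: "linear" or "relu" for the terminal layer; hidden
# layers are always ReLU. Returns activations needed for the backward pass.
mlp_forward <- function(layers, x, final = "linear") {
  L <- length(layers)
  h <- vector("list", L + 1L)
  a <- vector("list", L)
  h[[1L]] <- x
  for (l in seq_len(L)) {
    a[[l]] <- sweep(h[[l]] %*% t(layers[[l]]$W), 2L, layers[[l]]$b, "+")
    h[[l + 1L]] <- if (l < L || final == "relu") pmax(a[[l]], 0) else a[[l]]
  }
  list(h = h, a = a, out = h[[L + 1L]], final = final)
}

# Reverse pass: d_out is dLoss/d(output), same shape as cache$out.
# Returns list(grads = per-layer list(W, b), d_in = dLoss/d(input)).
mlp_backward <- function(layers, cache, d_out) {
  L <- length(layers)
  grads <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    if (l < L || cache$final == "relu") d <- d * (cache$a[[l]] > 0)
    grads[[l]] <- list(W = t(d) %*% cache$h[[l]], b = colSums(d))
    d <- d %*% layers[[l]]$W
  }
  list(grads = grads, d_in = d)
}

# Gradient of the network output w.r.t. its INPUT, one row per sample.
# Only valid for a scalar-output (final linear) network.
mlp_input_grad <- function(layers, cache) {
  L <- length(layers)
  n <- nrow(cache$out)
  v <- matrix(layers[[L]]$W, nrow = n, ncol = ncol(layers[[L]]$W),
              byrow = TRUE)
  for (l in rev(seq_len(L - 1L)))
    v <- (v * (cache$a[[l]] > 0)) %*% layers[[l]]$W
  v
}

adam_init <- function(layers) {
  lapply(layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

# One Adam update over a list of layers; returns list(layers, state, t).
adam_step <- function(layers, grads, state, t, lr, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# Elementwise sum of two gradient lists (same structure).
grads_add <- function(g1, g2) {
  for (l in seq_along(g1)) {
    g1[[l]]$W <- g1[[l]]$W + g2[[l]]$W
    g1[[l]]$b <- g1[[l]]$b + g2[[l]]$b
  }
  g1
}

grads_zero <- function(layers)
  lapply(layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
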