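# Minimal feed-forward network: tanh hidden layers, sigmoid output,
# binary cross-entropy loss, Adam optimizer. Written with plain matrix
# algebra; sized for desk-scale training (a few thousand cells, a few
# hundred to a few thousand features).

mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))    # Glorot uniform
    list(W = matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  n_layers <- length(layers)
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < n_layers) tanh(z) else 1 / (1 + exp(-z))
  }
  acts
}

# One Adam step on a minibatch; returns updated layers and moments.
mlp_step <- function(layers, moments, X, y, lr, l2 = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, t = 1) {
  acts <- mlp_forward(layers, X)
  n_layers <- length(layers)
  m <- nrow(X)
  # dL/dz for sigmoid + cross-entropy
  delta <- (acts[[n_layers + 1L]] - y) / m
  for (l in rev(seq_len(n_layers))) {
    gW <- crossprod(acts[[l]], delta) + l2 * layers[[l]]$W
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)  # tanh'
    }
    mo <- moments[[l]]
    mo$mW <- beta1 * mo$mW + (1 - beta1) * gW
    mo$vW <- beta2 * mo$vW + (1 - beta2) * gW^2
    mo$mb <- beta1 * mo$mb + (1 - beta1) * gb
    mo$vb <- beta2 * mo$vb + (1 - beta2) * gb^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    layers[[l]]$W <- layers[[l]]$W -
      lr * (mo$mW / corr1) / (sqrt(mo$vW / corr2) + eps)
    layers[[l]]$b <- layers[[l]]$b -
      lr * (mo$mb / corr1) / (sqrt(mo$vb / corr2) + eps)
    moments[[l]] <- mo
  }
  list(layers = layers, moments = moments)
}

# Train on X (units x features, already standardized), y in {0, 1}.
# Deterministic given the RNG state at entry.
mlp_train <- function(X, y, hidden = c(64L, 32L, 16L), epochs = 40L,
                      batch_size = 64L, lr = 1e-3, l2 = 1e-4) {
  stopifnot(nrow(X) == length(y))
  layers <- mlp_init(ncol(X), hidden)
  moments <- lapply(layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  n <- nrow(X)
  t_step <- 0
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      t_step <- t_step + 1
      upd <- mlp_step(layers, moments, X[idx, , drop = FALSE],
                      matrix(y[idx], ncol = 1L), lr, l2 = l2, t = t_step)
      layers <- upd$layers
      moments <- upd$moments
    }
  }
  structure(list(layers = layers, hidden = hidden, n_features = ncol(X)),
            class = "costimr_mlp")
}

mlp_prob <- function(net, X) {
  acts <- mlp_forward(net$layers, X)
  # clamp away from 0/1 so saturated logits never reach a degenerate
  # decision threshold exactly
  pmin(pmax(as.numeric(acts[[length(acts)]]), 1e-12), 1 - 1e-12)
}
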