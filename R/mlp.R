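# Compact multilayer perceptron in base R matrix algebra: tanh hidden
# layers, linear output, Adam updates. Sized for desk-scale experiments
# (hundreds of molecules, tens of features); all heavy lifting is BLAS GEMMs.

mlp_init <- function(n_in, hidden, n_out = 1L) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    fan_out <- sizes[i + 1L]
    sd0 <- sqrt(2 / (fan_in + fan_out))
    layers[[i]] <- list(
      W = matrix(rnorm(fan_in * fan_out, sd = sd0), fan_in, fan_out),
      b = numeric(fan_out)
    )
  }
  layers
}

act_fn <- function(z, activation) {
  switch(activation,
         tanh = tanh(z),
         softplus = log1p(exp(-abs(z))) + pmax(z, 0),
         abort(sprintf("unknown activation '%s'", activation)))
}

act_grad <- function(a, z, activation) {
  switch(activation,
         tanh = 1 - a^2,
         softplus = 1 / (1 + exp(-z)))
}

# returns list(out = n x n_out matrix, cache for backward)
mlp_forward <- function(layers, X, activation = "tanh") {
  L <- length(layers)
  As <- vector("list", L + 1L)
  Zs <- vector("list", L)
  As[[1L]] <- X
  for (i in seq_len(L)) {
    Z <- As[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    Zs[[i]] <- Z
    As[[i + 1L]] <- if (i < L) act_fn(Z, activation) else Z
  }
  list(out = As[[L + 1L]], As = As, Zs = Zs)
}

# dout: n x n_out matrix of dL/d(output); returns gradients per layer
mlp_backward <- function(layers, cache, dout, activation = "tanh") {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dout
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(cache$As[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) *
        act_grad(cache$As[[i]], cache$Zs[[i - 1L]], activation)
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
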