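# A small fully connected autoencoder trained with Adam.
#
# Architecture (fixed, matching the factor-importance analysis):
#   input d -> 200 -> 100 -> 50 (bottleneck) -> 100 -> 200 -> d
# ReLU on every hidden layer, linear output, mean squared error objective,
# full-batch Adam updates for at most `max_iter` epochs with early stopping
# on relative loss change.

mlp_autoencoder <- function(X, hidden = c(200, 100, 50, 100, 200),
                            max_iter = 25, lr = 1e-3,
                            seed = 1, tol = 1e-4,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  widths <- c(d, hidden, d)
  L <- length(widths) - 1  # number of weight layers

  init <- with_local_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(L)) {
      # He initialization for ReLU layers
      W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1],
                                    sd = sqrt(2 / widths[l])),
                       widths[l], widths[l + 1])
      b[[l]] <- rep(0, widths[l + 1])
    }
    list(W = W, b = b)
  })
  W <- init$W; b <- init$b
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb

  loss_tr <- numeric(0)
  t_step <- 0
  for (epoch in seq_len(max_iter)) {
    # forward
    act <- vector("list", L + 1)
    act[[1]] <- X
    for (l in seq_len(L)) {
      z <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+")
      act[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    err <- act[[L + 1]] - X
    loss <- mean(err^2)
    loss_tr <- c(loss_tr, loss)
    if (epoch > 1) {
      prev <- loss_tr[epoch - 1]
      if (abs(prev - loss) <= tol * max(prev, .Machine$double.eps)) break
    }
    # backward (d loss / d z for the output layer; MSE over all entries)
    delta <- 2 * err / (n * d)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(act[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
      }
    }
    # Adam update
    t_step <- t_step + 1
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      mhW <- mW[[l]] / (1 - beta1^t_step); vhW <- vW[[l]] / (1 - beta2^t_step)
      mhb <- mb[[l]] / (1 - beta1^t_step); vhb <- vb[[l]] / (1 - beta2^t_step)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  # final forward pass for latents and reconstruction
  act <- X
  latent <- NULL
  bottleneck_layer <- which(hidden == min(hidden))[1]
  for (l in seq_len(L)) {
    z <- sweep(act %*% W[[l]], 2, b[[l]], "+")
    act <- if (l < L) pmax(z, 0) else z
    if (l == bottleneck_layer) latent <- act
  }
  list(latent = latent, reconstruction = act, loss = loss_tr,
       final_loss = mean((act - X)^2), weights = W, biases = b)
}
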