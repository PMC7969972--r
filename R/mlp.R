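# Minimal feed-forward network for regression: rectifier hidden layers,
# mean-squared-error loss, mini-batch stochastic gradient descent with the
# ADADELTA per-weight adaptive step rule (rho = 0.99, eps = 1e-8). Written
# in plain matrix algebra; sized for a 6 -> 200 -> 200 -> 1 regressor.

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1L],
                            sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(layers)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < length(layers)) pmax(Z, 0) else Z
  }
  acts
}

mlp_train <- function(X, y, hidden = c(200, 200), epochs = 10,
                      batch_size = 32, rho = 0.99, eps = 1e-8, seed = 1) {
  stopifnot(nrow(X) == length(y))
  layers <- mlp_init(ncol(X), hidden, derive_seed(seed, 1))
  acc <- lapply(layers, function(l)
    list(Eg_W = l$W * 0, Ed_W = l$W * 0,
         Eg_b = l$b * 0, Ed_b = l$b * 0))
  n <- nrow(X)
  loss_trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 100 + epoch), sample.int(n))
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      m <- length(idx)
      acts <- mlp_forward(layers, Xb)
      pred <- acts[[length(acts)]][, 1L]
      err <- pred - yb
      epoch_loss <- epoch_loss + mean(err^2)
      n_batches <- n_batches + 1L
      # backprop (MSE): delta at output = 2 * err / m
      delta <- matrix(2 * err / m, m, 1L)
      for (l in rev(seq_along(layers))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        a <- acc[[l]]
        a$Eg_W <- rho * a$Eg_W + (1 - rho) * gW^2
        dW <- -sqrt(a$Ed_W + eps) / sqrt(a$Eg_W + eps) * gW
        a$Ed_W <- rho * a$Ed_W + (1 - rho) * dW^2
        a$Eg_b <- rho * a$Eg_b + (1 - rho) * gb^2
        db <- -sqrt(a$Ed_b + eps) / sqrt(a$Eg_b + eps) * gb
        a$Ed_b <- rho * a$Ed_b + (1 - rho) * db^2
        layers[[l]]$W <- layers[[l]]$W + dW
        layers[[l]]$b <- layers[[l]]$b + db
        acc[[l]] <- a
      }
    }
    loss_trace[epoch] <- epoch_loss / n_batches
  }
  list(layers = layers, loss_trace = loss_trace,
       hidden = hidden, epochs = epochs)
}

mlp_predict <- function(model, X) {
  acts <- mlp_forward(model$layers, X)
  acts[[length(acts)]][, 1L]
}
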