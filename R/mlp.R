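# Compact multilayer perceptron for binary classification.
#
# Feed-forward network with ReLU hidden layers and a logistic output,
# trained by full-batch Adam on the binary cross-entropy with L2 weight
# decay. Sized for the small-n wide-p tables this package works with;
# deliberately minimal (no dropout, no early stopping) and fully seeded.

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(layers)) {
    z <- acts[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < length(layers)) pmax(z, 0) else stats::plogis(z)
  }
  acts
}

mlp_fit <- function(X, y, hidden = c(64, 32, 16), epochs = 200,
                    learning_rate = 0.01, weight_decay = 1e-4, seed = 1L) {
  stopifnot(is.matrix(X), all(y %in% c(0, 1)))
  n <- nrow(X)
  layers <- mlp_init(ncol(X), hidden, seed)
  L <- length(layers)
  m <- v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  for (epoch in seq_len(epochs)) {
    acts <- mlp_forward(layers, X)
    delta <- (acts[[L + 1L]] - y) / n          # d(BCE)/dz at logistic output
    t <- t + 1
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta) + weight_decay * layers[[l]]$W
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
      }
      m[[l]]$W <- beta1 * m[[l]]$W + (1 - beta1) * gW
      m[[l]]$b <- beta1 * m[[l]]$b + (1 - beta1) * gb
      v[[l]]$W <- beta2 * v[[l]]$W + (1 - beta2) * gW^2
      v[[l]]$b <- beta2 * v[[l]]$b + (1 - beta2) * gb^2
      corr <- learning_rate * sqrt(1 - beta2^t) / (1 - beta1^t)
      layers[[l]]$W <- layers[[l]]$W - corr * m[[l]]$W / (sqrt(v[[l]]$W) + eps)
      layers[[l]]$b <- layers[[l]]$b - corr * m[[l]]$b / (sqrt(v[[l]]$b) + eps)
    }
  }
  structure(list(layers = layers, hidden = hidden), class = "emlscreen_mlp")
}

mlp_predict <- function(model, X) {
  acts <- mlp_forward(model$layers, X)
  as.numeric(acts[[length(acts)]])
}
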