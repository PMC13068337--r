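# Minimal full-batch neural-network machinery (Adam optimizer) used by the
# feed-forward and autoencoder regressors. Deliberately small: dense layers,
# ReLU, inverted dropout, mean-squared-error loss, all deterministic under a
# caller-supplied seed.

nn_init <- function(sizes, seed) {
  set.seed(seed)
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[i]
    params[[paste0("W", i)]] <- matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sqrt(2 / fan_in)),
                                       fan_in, sizes[i + 1])
    params[[paste0("b", i)]] <- rep(0, sizes[i + 1])
  }
  params
}

nn_forward <- function(params, X, dropout = 0, training = FALSE) {
  L <- length(params) / 2L
  a <- X
  cache <- list(a0 = X)
  for (i in seq_len(L)) {
    z <- sweep(a %*% params[[paste0("W", i)]], 2, params[[paste0("b", i)]], `+`)
    if (i < L) {
      a <- pmax(z, 0)
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
        a <- a * mask
        cache[[paste0("mask", i)]] <- mask
      }
      cache[[paste0("z", i)]] <- z
      cache[[paste0("a", i)]] <- a
    } else {
      a <- z
    }
  }
  cache$out <- a
  cache
}

nn_backward <- function(params, cache, Y, dropout = 0) {
  L <- length(params) / 2L
  n <- nrow(Y)
  grads <- list()
  delta <- 2 * (cache$out - Y) / (n * ncol(Y))
  for (i in rev(seq_len(L))) {
    a_prev <- cache[[paste0("a", i - 1L)]] %||% cache$a0
    if (i > 1L && is.null(cache[[paste0("a", i - 1L)]])) a_prev <- cache$a0
    grads[[paste0("W", i)]] <- crossprod(a_prev, delta)
    grads[[paste0("b", i)]] <- colSums(delta)
    if (i > 1L) {
      delta <- delta %*% t(params[[paste0("W", i)]])
      mask <- cache[[paste0("mask", i - 1L)]]
      if (!is.null(mask)) delta <- delta * mask
      delta <- delta * (cache[[paste0("z", i - 1L)]] > 0)
    }
  }
  grads
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * grads[[nm]]
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

# train a multi-output feed-forward regressor; val_idx rows (if any) are
# held out for early stopping and never contribute to gradients
nn_train <- function(X, Y, hidden = c(256, 128), epochs = 300, lr = 1e-3,
                     dropout = 0.1, seed = 0, val_idx = NULL, patience = 30) {
  sizes <- c(ncol(X), hidden, ncol(Y))
  params <- nn_init(sizes, seed)
  set.seed(seed + 1L)
  Xtr <- X; Ytr <- Y; Xva <- NULL
  if (length(val_idx)) {
    Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]
    Xtr <- X[-val_idx, , drop = FALSE]; Ytr <- Y[-val_idx, , drop = FALSE]
  }
  opt <- adam_new(params, lr = lr)
  best <- list(loss = Inf, params = params, epoch = 0)
  history <- numeric(0)
  stale <- 0
  for (ep in seq_len(epochs)) {
    cache <- nn_forward(params, Xtr, dropout = dropout, training = TRUE)
    grads <- nn_backward(params, cache, Ytr, dropout = dropout)
    st <- adam_step(opt, params, grads)
    opt <- st$opt; params <- st$params
    monitor <- if (is.null(Xva)) {
      mean((nn_forward(params, Xtr)$out - Ytr)^2)
    } else {
      mean((nn_forward(params, Xva)$out - Yva)^2)
    }
    if (!is.finite(monitor)) {
      stop(sprintf("non-finite loss at epoch %d (last finite: %.4g)", ep,
                   if (length(history)) history[length(history)] else NA_real_), call. = FALSE)
    }
    history <- c(history, monitor)
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = params, epoch = ep)
      stale <- 0
    } else {
      stale <- stale + 1
      if (!is.null(Xva) && stale >= patience) break
    }
  }
  list(params = if (is.null(Xva)) params else best$params,
       history = history, best_epoch = best$epoch)
}

nn_predict_mat <- function(params, X) nn_forward(params, X)$out

# joint-loss autoencoder: linear encoder to a latent space, linear decoder
# for reconstruction, linear head for regression; loss = MSE_recon +
# lambda * MSE_regress. Returns encoder weights and loss curves.
ae_train <- function(X, Y, latent_dim, lambda = 1, epochs = 500, lr = 1e-2, seed = 0) {
  if (latent_dim >= ncol(X)) {
    stop("latent dimension (", latent_dim, ") must be below the input dimension (",
         ncol(X), ")", call. = FALSE)
  }
  set.seed(seed)
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  params <- list(
    We = matrix(stats::rnorm(p * latent_dim, sd = 1 / sqrt(p)), p, latent_dim),
    be = rep(0, latent_dim),
    Wd = matrix(stats::rnorm(latent_dim * p, sd = 1 / sqrt(latent_dim)), latent_dim, p),
    bd = rep(0, p),
    Wr = matrix(stats::rnorm(latent_dim * q, sd = 1 / sqrt(latent_dim)), latent_dim, q),
    br = rep(0, q))
  opt <- adam_new(params, lr = lr)
  recon <- numeric(epochs); regress <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    Z <- sweep(X %*% params$We, 2, params$be, `+`)
    Xhat <- sweep(Z %*% params$Wd, 2, params$bd, `+`)
    Yhat <- sweep(Z %*% params$Wr, 2, params$br, `+`)
    Rx <- Xhat - X
    Ry <- Yhat - Y
    recon[ep] <- mean(Rx^2)
    regress[ep] <- mean(Ry^2)
    dXhat <- 2 * Rx / (n * p)
    dYhat <- if (lambda > 0) 2 * lambda * Ry / (n * q) else matrix(0, n, q)
    dZ <- dXhat %*% t(params$Wd) + dYhat %*% t(params$Wr)
    grads <- list(
      We = crossprod(X, dZ), be = colSums(dZ),
      Wd = crossprod(Z, dXhat), bd = colSums(dXhat),
      Wr = crossprod(Z, dYhat), br = colSums(dYhat))
    st <- adam_step(opt, params, grads)
    opt <- st$opt; params <- st$params
  }
  list(params = params, recon_loss = recon, regress_loss = regress)
}

ae_encode <- function(ae, X) sweep(X %*% ae$params$We, 2, ae$params$be, `+`)
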