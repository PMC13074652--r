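# Minimal feed-forward network machinery shared by the tabular VAE and the
# FFNN regressor: dense, batch-normalization, activation and dropout layers
# with explicit backpropagation and an Adam optimizer. Matrices are stored
# feature-per-row / sample-per-column, so per-feature vector operations use
# R's native column-major recycling without intermediate allocations. All
# randomness (initialization, dropout masks) is drawn from the current RNG
# stream, so callers control determinism via set.seed.

nn_dense <- function(n_in, n_out) {
  list(
    type = "dense",
    W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_out, n_in),
    b = rep(0, n_out)
  )
}

nn_bn <- function(dim, momentum = 0.1, eps = 1e-5) {
  list(
    type = "bn", gamma = rep(1, dim), beta = rep(0, dim),
    run_mean = rep(0, dim), run_var = rep(1, dim),
    momentum = momentum, eps = eps
  )
}

nn_act <- function(kind = c("relu", "lrelu")) {
  list(type = "act", kind = match.arg(kind), slope = 0.01)
}

nn_dropout <- function(p) list(type = "dropout", p = p)

# Forward pass through a list of layers; X is features x samples. Returns
# the output, per-layer caches for backprop, and the (possibly updated)
# layers — batch-norm running statistics are updated in training mode.
nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- ly$W %*% X + ly$b
    } else if (ly$type == "bn") {
      if (training) {
        mu <- rowMeans(X)
        xc <- X - mu
        va <- rowMeans(xc^2)
        inv_sd <- 1 / sqrt(va + ly$eps)
        xhat <- xc * inv_sd
        ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
        ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * va
        layers[[i]] <- ly
        caches[[i]] <- list(xc = xc, inv_sd = inv_sd, xhat = xhat)
      } else {
        xhat <- (X - ly$run_mean) / sqrt(ly$run_var + ly$eps)
        caches[[i]] <- list(xhat = xhat)
      }
      X <- xhat * ly$gamma + ly$beta
    } else if (ly$type == "act") {
      slope <- if (ly$kind == "relu") 0 else ly$slope
      scale <- slope + (1 - slope) * (X > 0)
      caches[[i]] <- list(scale = scale)
      X <- X * scale
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- (matrix(stats::runif(length(X)), nrow(X)) >= ly$p) / (1 - ly$p)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    }
  }
  list(out = X, caches = caches, layers = layers)
}

# Backward pass; returns the gradient w.r.t. the input and per-layer
# parameter gradients (NULL for parameter-free layers).
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(W = tcrossprod(dout, ca$X), b = rowSums(dout))
      dout <- crossprod(ly$W, dout)
    } else if (ly$type == "bn") {
      if (is.null(ca$xc)) stop("batch-norm backward requires a training-mode cache")
      N <- ncol(ca$xhat)
      dgamma <- rowSums(dout * ca$xhat)
      dbeta <- rowSums(dout)
      dxhat <- dout * ly$gamma
      dvar <- rowSums(dxhat * ca$xc) * (-0.5) * ca$inv_sd^3
      dmu <- rowSums(dxhat) * (-ca$inv_sd) + dvar * rowMeans(-2 * ca$xc)
      dout <- dxhat * ca$inv_sd + ca$xc * (2 * dvar / N) + dmu / N
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (ly$type == "act") {
      dout <- dout * ca$scale
      grads[i] <- list(NULL)
    } else if (ly$type == "dropout") {
      if (!is.null(ca$mask)) dout <- dout * ca$mask
      grads[i] <- list(NULL)
    }
  }
  list(dX = dout, grads = grads)
}

nn_param_names <- function(layer) {
  switch(layer$type, dense = c("W", "b"), bn = c("gamma", "beta"), character(0))
}

nn_adam_init <- function(layers) {
  lapply(layers, function(ly) {
    nms <- nn_param_names(ly)
    if (!length(nms)) return(NULL)
    st <- lapply(nms, function(nm) list(m = ly[[nm]] * 0, v = ly[[nm]] * 0))
    names(st) <- nms
    st
  })
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 / (1 - beta1^t)
  c2 <- 1 / (1 - beta2^t)
  for (i in seq_along(layers)) {
    nms <- nn_param_names(layers[[i]])
    if (!length(nms) || is.null(grads[[i]])) next
    for (nm in nms) {
      g <- grads[[i]][[nm]]
      s <- state[[i]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * (s$m * c1) / (sqrt(s$v * c2) + eps)
      state[[i]][[nm]] <- s
    }
  }
  list(layers = layers, state = state)
}

# Minibatch index list for one epoch (shuffled). A trailing singleton batch
# is merged into its predecessor because batch normalization is degenerate
# on a single sample.
nn_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  nb <- ceiling(n / batch_size)
  b <- lapply(seq_len(nb), function(k) {
    idx[(((k - 1L) * batch_size + 1L)):min(k * batch_size, n)]
  })
  if (nb > 1L && length(b[[nb]]) == 1L) {
    b[[nb - 1L]] <- c(b[[nb - 1L]], b[[nb]])
    b[[nb]] <- NULL
  }
  b
}
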