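#' Hyperparameters of the feed-forward network regressor
#'
#' Two hidden layers (32 and 8 units), each followed by batch normalization,
#' rectifier activation and dropout; a single linear output unit; mean
#' squared error loss minimized with Adam; at most `epochs` epochs with early
#' stopping when the validation loss has not improved for `patience`
#' consecutive epochs.
#'
#' @param hidden hidden layer sizes.
#' @param dropout dropout rate.
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs); must be below `epochs`.
#' @param batch_size minibatch size.
#' @param val_fraction validation fraction used when no explicit validation
#'   split is supplied (last 20% of a seeded shuffle).
#' @return a list of class `ffnn_config`.
#' @export
ffnn_config <- function(hidden = c(32L, 8L), dropout = 0.2, lr = 1e-3,
                        epochs = 500L, patience = 80L, batch_size = 256L,
                        val_fraction = 0.2) {
  if (patience >= epochs) stop_config("patience", "must be below epochs")
  if (any(hidden <= 0)) stop_config("hidden", "sizes must be positive")
  structure(
    list(
      hidden = hidden, dropout = dropout, lr = lr, epochs = epochs,
      patience = patience, batch_size = batch_size, val_fraction = val_fraction
    ),
    class = "ffnn_config"
  )
}

#' Train the feed-forward network regressor
#'
#' Features and target are z-scored on training statistics. If `X_val` is
#' `NULL`, the last `val_fraction` of a seeded shuffle of the training rows
#' is held out for early stopping. The weights of the best validation epoch
#' are kept. A constant target short-circuits to a constant predictor.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric target vector.
#' @param X_val,y_val optional validation split (must contain no synthetic
#'   rows; the caller is responsible for that).
#' @param config an [ffnn_config()].
#' @param seed integer seed.
#' @return an object of class `pepper_ffnn` with `stop_epoch`, `best_epoch`
#'   and the train/validation loss `trace`.
#' @export
train_ffnn <- function(X, y, X_val = NULL, y_val = NULL,
                       config = ffnn_config(), seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[!is.finite(x_scale) | x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  base <- list(
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale, features = colnames(X)
  )
  if (!is.finite(y_scale) || y_scale == 0) {
    return(structure(
      c(base, list(constant = y_center, layers = NULL, stop_epoch = 0L,
                   best_epoch = 0L, trace = NULL)),
      class = "pepper_ffnn"
    ))
  }
  scale_x <- function(M) sweep(sweep(as.matrix(M), 2, x_center), 2, x_scale, `/`)

  with_seed(seed, {
    if (is.null(X_val)) {
      n <- nrow(X)
      idx <- sample.int(n)
      n_val <- max(1L, floor(config$val_fraction * n))
      val_idx <- idx[(n - n_val + 1L):n]
      tr_idx <- idx[seq_len(n - n_val)]
      X_val <- X[val_idx, , drop = FALSE]; y_val <- y[val_idx]
      X <- X[tr_idx, , drop = FALSE]; y <- y[tr_idx]
    }
    Xs <- t(scale_x(X)) # features x samples
    ys <- (y - y_center) / y_scale
    Xv <- t(scale_x(X_val))
    yv <- (y_val - y_center) / y_scale

    h <- config$hidden
    layers <- list(
      nn_dense(nrow(Xs), h[1]), nn_bn(h[1]), nn_act("relu"), nn_dropout(config$dropout),
      nn_dense(h[1], h[2]), nn_bn(h[2]), nn_act("relu"), nn_dropout(config$dropout),
      nn_dense(h[2], 1L)
    )
    st <- nn_adam_init(layers)
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    wait <- 0L
    t_step <- 0L
    trace <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
    ntr <- ncol(Xs)
    stop_epoch <- config$epochs
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (bi in nn_batches(ntr, config$batch_size)) {
        xb <- Xs[, bi, drop = FALSE]
        yb <- ys[bi]
        fw <- nn_forward(layers, xb, training = TRUE)
        layers <- fw$layers
        resid <- drop(fw$out) - yb
        ep_loss <- ep_loss + sum(resid^2)
        dout <- matrix(2 * resid / length(bi), nrow = 1L)
        bw <- nn_backward(layers, fw$caches, dout)
        t_step <- t_step + 1L
        up <- nn_adam_step(layers, bw$grads, st, config$lr, t_step)
        layers <- up$layers; st <- up$state
      }
      val_pred <- drop(nn_forward(layers, Xv, training = FALSE)$out)
      val_loss <- mean((val_pred - yv)^2)
      trace <- rbind(trace, data.frame(epoch = ep, train = ep_loss / ntr, val = val_loss))
      if (is.finite(val_loss) && val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, layers = layers, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          stop_epoch <- ep
          break
        }
      }
    }
    structure(
      c(base, list(
        constant = NULL, layers = best$layers, stop_epoch = stop_epoch,
        best_epoch = best$epoch, trace = trace, config = config
      )),
      class = "pepper_ffnn"
    )
  })
}

#' @export
predict.pepper_ffnn <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(X)))
  Xs <- t(sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`))
  drop(nn_forward(object$layers, Xs, training = FALSE)$out) * object$y_scale + object$y_center
}
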