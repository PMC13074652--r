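#' Hyperparameters of the tabular variational autoencoder
#'
#' Encoder and decoder are fully connected networks with two hidden layers
#' each (64 and 32 units), per-layer batch normalization, leaky-rectifier
#' activation and dropout. The encoder outputs a latent mean \eqn{\mu} and
#' log-variance \eqn{\log\sigma^2}; latent draws use the reparameterization
#' trick \eqn{z = \mu + e^{\log\sigma^2/2}\,\epsilon}. The training loss is
#' mean squared reconstruction error plus \eqn{\lambda \cdot
#' KL(q(z|x)\,\|\,N(0, I))}.
#'
#' @param latent_dim latent dimension.
#' @param hidden hidden layer sizes (encoder order; the decoder mirrors them).
#' @param epochs training epochs (trained exactly this many).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param kl_weight KL weight \eqn{\lambda}.
#' @param dropout dropout rate.
#' @return a list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 8L, hidden = c(64L, 32L), epochs = 500L,
                       batch_size = 32L, lr = 1e-3, kl_weight = 0.1,
                       dropout = 0.1) {
  cfg <- list(
    latent_dim = latent_dim, hidden = hidden, epochs = epochs,
    batch_size = batch_size, lr = lr, kl_weight = kl_weight, dropout = dropout
  )
  if (any(unlist(cfg[c("latent_dim", "hidden", "epochs", "batch_size", "lr")]) <= 0)) {
    stop_config("vae_config", "all sizes, epochs and learning rate must be positive")
  }
  class(cfg) <- "vae_config"
  cfg
}

# Analytic KL(q(z|x) || N(0,I)) per sample, averaged over the batch.
# mu and logvar are latent-dim x batch matrices.
vae_kl_term <- function(mu, logvar) {
  mean(colSums(-0.5 * (1 + logvar - mu^2 - exp(logvar))))
}

#' Train a variational autoencoder on one augmentation group
#'
#' Continuous features are z-scored within the group before training
#' (constant features are kept at zero); trained for exactly
#' `config$epochs` epochs with Adam; the per-epoch loss trace (reconstruction
#' MSE plus \eqn{\lambda}-weighted KL) is recorded. Deterministic given
#' `seed`.
#'
#' @param group data.frame of original records from one (season, treatment,
#'   DAT) group.
#' @param config a [vae_config()].
#' @param features continuous columns to model (default: the eight traits
#'   plus both FW targets).
#' @param n_thr routing threshold: groups of `n <= n_thr` must use the
#'   Gaussian path and are rejected here.
#' @param seed integer seed.
#' @return an object of class `pepper_vae` with the trained encoder/decoder,
#'   the within-group scaler, the loss `trace` and the source group info.
#' @export
train_vae <- function(group, config = vae_config(),
                      features = c(TRAIT_COLUMNS, TARGET_COLUMNS),
                      n_thr = 10L, seed = 1L) {
  n <- nrow(group)
  if (n <= n_thr) {
    stop(sprintf(
      "group of size %d is not above the VAE threshold (n_thr = %d); use the Gaussian path",
      n, n_thr
    ), call. = FALSE)
  }
  X_raw <- as.matrix(group[, features, drop = FALSE])
  d <- ncol(X_raw)
  if (config$latent_dim >= d) stop_config("latent_dim", "must be smaller than the input dimension")
  center <- colMeans(X_raw)
  scale_ <- apply(X_raw, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  X <- t(sweep(sweep(X_raw, 2, center), 2, scale_, `/`)) # features x samples

  with_seed(seed, {
    h <- config$hidden
    ld <- config$latent_dim
    trunk <- list(
      nn_dense(d, h[1]), nn_bn(h[1]), nn_act("lrelu"), nn_dropout(config$dropout),
      nn_dense(h[1], h[2]), nn_bn(h[2]), nn_act("lrelu"), nn_dropout(config$dropout)
    )
    head_mu <- list(nn_dense(h[2], ld))
    head_lv <- list(nn_dense(h[2], ld))
    decoder <- list(
      nn_dense(ld, h[2]), nn_bn(h[2]), nn_act("lrelu"), nn_dropout(config$dropout),
      nn_dense(h[2], h[1]), nn_bn(h[1]), nn_act("lrelu"), nn_dropout(config$dropout),
      nn_dense(h[1], d)
    )
    st <- list(
      trunk = nn_adam_init(trunk), mu = nn_adam_init(head_mu),
      lv = nn_adam_init(head_lv), dec = nn_adam_init(decoder)
    )
    lam <- config$kl_weight
    trace <- numeric(config$epochs)
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      ep_n <- 0L
      for (bi in nn_batches(n, config$batch_size)) {
        xb <- X[, bi, drop = FALSE]
        nb <- length(bi)
        f_tr <- nn_forward(trunk, xb, training = TRUE); trunk <- f_tr$layers
        f_mu <- nn_forward(head_mu, f_tr$out, training = TRUE)
        f_lv <- nn_forward(head_lv, f_tr$out, training = TRUE)
        mu <- f_mu$out; logvar <- f_lv$out
        epsm <- matrix(stats::rnorm(ld * nb), ld, nb)
        z <- mu + exp(logvar / 2) * epsm
        f_de <- nn_forward(decoder, z, training = TRUE); decoder <- f_de$layers
        xhat <- f_de$out

        recon <- mean((xhat - xb)^2)
        kl <- vae_kl_term(mu, logvar)
        loss <- recon + lam * kl
        ep_loss <- ep_loss + loss * nb
        ep_n <- ep_n + nb

        # backprop: reconstruction into the decoder, then through the
        # reparameterized z into both heads, plus the analytic KL gradients
        dxhat <- 2 * (xhat - xb) / (nb * d)
        b_de <- nn_backward(decoder, f_de$caches, dxhat)
        dz <- b_de$dX
        dmu <- dz + lam * mu / nb
        dlv <- dz * epsm * exp(logvar / 2) / 2 + lam * 0.5 * (exp(logvar) - 1) / nb
        b_mu <- nn_backward(head_mu, f_mu$caches, dmu)
        b_lv <- nn_backward(head_lv, f_lv$caches, dlv)
        b_tr <- nn_backward(trunk, f_tr$caches, b_mu$dX + b_lv$dX)

        t_step <- t_step + 1L
        up <- nn_adam_step(decoder, b_de$grads, st$dec, config$lr, t_step)
        decoder <- up$layers; st$dec <- up$state
        up <- nn_adam_step(head_mu, b_mu$grads, st$mu, config$lr, t_step)
        head_mu <- up$layers; st$mu <- up$state
        up <- nn_adam_step(head_lv, b_lv$grads, st$lv, config$lr, t_step)
        head_lv <- up$layers; st$lv <- up$state
        up <- nn_adam_step(trunk, b_tr$grads, st$trunk, config$lr, t_step)
        trunk <- up$layers; st$trunk <- up$state
      }
      trace[ep] <- ep_loss / ep_n
      if (!is.finite(trace[ep])) {
        stop(sprintf("VAE training diverged at epoch %d (loss %.3g)", ep, trace[ep]), call. = FALSE)
      }
    }
    structure(
      list(
        decoder = decoder, trunk = trunk, head_mu = head_mu, head_lv = head_lv,
        center = center, scale = scale_, features = features,
        group_key = record_group_key(group[1L, ]), group = group,
        n_group = n, config = config, trace = trace
      ),
      class = "pepper_vae"
    )
  })
}

#' Sample synthetic records from a trained VAE
#'
#' Draws latent vectors from a standard normal, decodes them in inference
#' mode (running batch-norm statistics, no dropout), de-standardizes with the
#' group's mean/sd, clips at zero below, and reassigns the categorical and
#' discrete fields (year, season, cultivar, treatment, DAT, pruning) from the
#' source group. At most `10 x` the group size may be drawn.
#'
#' @param vae a trained [train_vae()] generator.
#' @param m number of synthetic records.
#' @param seed integer seed.
#' @param max_factor generation cap as a multiple of the group size.
#' @return a data.frame of synthetic plant records (`is_synthetic = TRUE`,
#'   `source_group` set) with attribute `generator = "vae"`.
#' @export
sample_vae <- function(vae, m, seed = 1L, max_factor = 10) {
  stopifnot(inherits(vae, "pepper_vae"))
  if (m > max_factor * vae$n_group) {
    stop(sprintf(
      "requested %d synthetic samples exceeds the cap of %d (%gx group size %d)",
      m, max_factor * vae$n_group, max_factor, vae$n_group
    ), call. = FALSE)
  }
  feats <- vae$features
  if (m == 0L) {
    out <- vae$group[0L, , drop = FALSE]
    attr(out, "generator") <- "vae"
    return(out)
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(m * vae$config$latent_dim), vae$config$latent_dim, m)
    xhat <- t(nn_forward(vae$decoder, z, training = FALSE)$out)
    X <- sweep(sweep(xhat, 2, vae$scale, `*`), 2, vae$center, `+`)
    X <- pmax(X, 0)
    src <- vae$group[sample.int(vae$n_group, m, replace = TRUE), , drop = FALSE]
    out <- src
    out[, feats] <- X
    out$is_synthetic <- TRUE
    out$source_group <- vae$group_key
    rownames(out) <- NULL
    attr(out, "generator") <- "vae"
    out
  })
}
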