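#' Configuration of the group-wise augmentation
#'
#' Augmentation runs independently within each (season, treatment, DAT)
#' group: groups of `n <= n_thr` records are expanded by resampling plus
#' additive Gaussian noise at `noise_scale` times the within-group
#' feature-wise standard deviation; larger groups train a variational
#' autoencoder. At most `max_factor` synthetic records per original record
#' are ever generated.
#'
#' @param n_thr group-size threshold routing Gaussian vs. VAE.
#' @param noise_scale Gaussian noise scale `c` (multiplier on the
#'   feature-wise sd).
#' @param factor generation factor (synthetic records per original record).
#' @param max_factor hard cap on `factor`.
#' @param features continuous columns fed to the generative process (the
#'   eight traits plus both FW targets by default; switch targets off by
#'   passing only the traits).
#' @param vae a [vae_config()].
#' @param seed master seed; per-group streams are derived with
#'   [group_seed()] so results are independent of group order.
#' @return a list of class `augmentation_config`.
#' @export
augmentation_config <- function(n_thr = 10L, noise_scale = 0.05, factor = 10,
                                max_factor = 10,
                                features = c(TRAIT_COLUMNS, TARGET_COLUMNS),
                                vae = vae_config(), seed = 1L) {
  if (n_thr < 1) stop_config("n_thr", "must be >= 1")
  if (noise_scale <= 0) stop_config("noise_scale", "must be > 0")
  if (factor < 1) stop_config("factor", "must be >= 1")
  if (factor > max_factor) {
    stop_config("factor", sprintf("must not exceed the cap of %g", max_factor))
  }
  structure(
    list(
      n_thr = n_thr, noise_scale = noise_scale, factor = factor,
      max_factor = max_factor, features = features, vae = vae, seed = seed
    ),
    class = "augmentation_config"
  )
}

#' Partition original records into augmentation groups
#'
#' Disjoint, exhaustive partition of the non-synthetic records by
#' (season, treatment, DAT), keyed as `"season|treatment|dat"`.
#'
#' @param records plant-record data.frame.
#' @return named list of record subsets; each element carries the attribute
#'   `row_idx` with the row indices into `records`.
#' @export
partition_groups <- function(records) {
  orig_idx <- which(!records$is_synthetic)
  if (!length(orig_idx)) return(stats::setNames(list(), character(0)))
  keys <- record_group_key(records[orig_idx, , drop = FALSE])
  out <- lapply(split(orig_idx, keys), function(ix) {
    g <- records[ix, , drop = FALSE]
    attr(g, "row_idx") <- ix
    g
  })
  out[order(names(out))]
}

#' Gaussian-noise augmentation for small groups
#'
#' Samples original rows uniformly with replacement and perturbs each
#' continuous feature with additive zero-mean Gaussian noise of standard
#' deviation `noise_scale` times that feature's within-group sd (constant
#' features stay constant). Categorical and discrete fields are copied from
#' the sampled row; values are clipped at zero below.
#'
#' @param group data.frame of original records from one group.
#' @param factor synthetic records per original record.
#' @param seed integer seed.
#' @param noise_scale noise scale on the feature-wise sd.
#' @param features continuous columns to perturb.
#' @param max_factor generation cap.
#' @return data.frame of synthetic records (`is_synthetic = TRUE`) with
#'   attributes `generator = "gaussian"` and `source_idx` (row index of each
#'   synthetic row's source within `group`).
#' @export
augment_gaussian <- function(group, factor = 10, seed = 1L, noise_scale = 0.05,
                             features = c(TRAIT_COLUMNS, TARGET_COLUMNS),
                             max_factor = 10) {
  n <- nrow(group)
  stopifnot(n >= 1L)
  if (factor > max_factor) {
    stop_config("factor", sprintf("must not exceed the cap of %g", max_factor))
  }
  m <- round(factor * n)
  sds <- vapply(features, function(f) stats::sd(group[[f]]), numeric(1))
  sds[!is.finite(sds)] <- 0
  with_seed(seed, {
    src <- sample.int(n, m, replace = TRUE)
    out <- group[src, , drop = FALSE]
    for (j in seq_along(features)) {
      f <- features[j]
      out[[f]] <- pmax(0, out[[f]] + stats::rnorm(m, 0, noise_scale * sds[j]))
    }
    out$is_synthetic <- TRUE
    out$source_group <- record_group_key(group[1L, ])
    rownames(out) <- NULL
    attr(out, "generator") <- "gaussian"
    attr(out, "source_idx") <- src
    out
  })
}

#' Marginal KL divergence between two samples
#'
#' Histogram estimate of \eqn{KL(\mathrm{original}\,\|\,\mathrm{augmented})}
#' in nats: `bins` equal-width bins over the pooled min-max range, additive
#' smoothing `eps` on both histograms before normalization. Degenerate
#' pooled ranges (all values identical) give 0.
#'
#' @param original,augmented numeric vectors (non-empty).
#' @param bins number of bins.
#' @param eps additive smoothing count.
#' @return scalar KL divergence (>= 0 up to smoothing noise).
#' @export
kl_divergence_marginal <- function(original, augmented, bins = 20L, eps = 1e-8) {
  if (!length(original) || !length(augmented)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- range(c(original, augmented), finite = TRUE)
  if (diff(pooled) == 0) return(0)
  edges <- seq(pooled[1], pooled[2], length.out = bins + 1L)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins)
  p <- tabulate(bin_of(original), bins) + eps
  q <- tabulate(bin_of(augmented), bins) + eps
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Feature-averaged KL divergence between original and synthetic records
#'
#' @param original original records.
#' @param synthetic synthetic records.
#' @param features continuous columns to compare.
#' @param bins,eps passed to [kl_divergence_marginal()].
#' @return list with `per_feature` (named vector, nats) and `mean`.
#' @export
feature_kl <- function(original, synthetic,
                       features = c(TRAIT_COLUMNS, TARGET_COLUMNS),
                       bins = 20L, eps = 1e-8) {
  per <- vapply(features, function(f) {
    kl_divergence_marginal(original[[f]], synthetic[[f]], bins = bins, eps = eps)
  }, numeric(1))
  list(per_feature = per, mean = mean(per))
}

#' Group-wise augmentation of a record table
#'
#' Applies the Gaussian path to groups of `n <= n_thr` and the VAE path to
#' larger groups, each generating `factor` synthetic records per original.
#' Original rows are returned untouched, with the synthetic rows appended
#' (`is_synthetic = TRUE`, `source_group` set to the group key). Per-group
#' failures are reported with the group key in the message.
#'
#' @param records original plant records (no synthetic rows).
#' @param config an [augmentation_config()].
#' @return the combined record table with attribute `augmentation`: a list
#'   with per-group `generator`, original/synthetic counts, source row
#'   indices (into `records`), and VAE loss traces.
#' @export
augment_dataset <- function(records, config = augmentation_config()) {
  if (any(records$is_synthetic)) {
    stop("augment_dataset expects original records only", call. = FALSE)
  }
  groups <- partition_groups(records)
  synth <- list()
  info <- list()
  for (key in names(groups)) {
    g <- groups[[key]]
    n <- nrow(g)
    seed_g <- group_seed(config$seed, key)
    res <- tryCatch(
      {
        if (n <= config$n_thr) {
          batch <- augment_gaussian(
            g, factor = config$factor, seed = seed_g,
            noise_scale = config$noise_scale, features = config$features,
            max_factor = config$max_factor
          )
          list(batch = batch, generator = "gaussian", trace = NULL,
               source_idx = attr(g, "row_idx")[attr(batch, "source_idx")])
        } else {
          vae <- train_vae(g, config = config$vae, features = config$features,
                           n_thr = config$n_thr, seed = seed_g)
          m <- min(round(config$factor * n), round(config$max_factor * n))
          batch <- sample_vae(vae, m, seed = seed_g + 1L,
                              max_factor = config$max_factor)
          list(batch = batch, generator = "vae", trace = vae$trace,
               source_idx = attr(g, "row_idx"))
        }
      },
      error = function(e) {
        stop(sprintf("augmentation failed for group '%s': %s", key, conditionMessage(e)),
             call. = FALSE)
      }
    )
    synth[[key]] <- res$batch
    info[[key]] <- list(
      key = key, generator = res$generator, n_orig = n, n_synth = nrow(res$batch),
      source_idx = res$source_idx, trace = res$trace
    )
  }
  synth_df <- if (length(synth)) do.call(rbind, c(synth, list(make.row.names = FALSE))) else records[0L, ]
  out <- rbind(records, synth_df, make.row.names = FALSE)
  attr(out, "augmentation") <- info
  out
}

#' Sweep the Gaussian/VAE routing threshold
#'
#' Runs the full augmentation under each candidate threshold and scores each
#' by the feature-averaged KL divergence between the original records and
#' the synthetic records. Returns the candidate minimizing the mean KL, with
#' ties broken toward the larger threshold. If no group exceeds the largest
#' candidate the sweep degenerates (all candidates Gaussian-only); a warning
#' is issued and the tie rule applies.
#'
#' @param records original plant records.
#' @param candidates candidate thresholds.
#' @param config base [augmentation_config()]; `n_thr` is overridden per
#'   candidate.
#' @return list with `n_thr` (chosen threshold) and `table` (data.frame of
#'   `candidate`, `mean_kl`, sorted by candidate).
#' @export
select_threshold <- function(records, candidates = c(3L, 5L, 7L, 10L),
                             config = augmentation_config()) {
  stopifnot(length(candidates) >= 1L)
  candidates <- sort(candidates)
  sizes <- vapply(partition_groups(records), nrow, integer(1))
  if (!any(sizes > max(candidates))) {
    warning("no group exceeds the largest candidate threshold; the sweep is Gaussian-only")
  }
  mean_kl <- vapply(candidates, function(thr) {
    cfg <- config
    cfg$n_thr <- thr
    aug <- augment_dataset(records, cfg)
    feature_kl(records, aug[aug$is_synthetic, , drop = FALSE],
               features = config$features)$mean
  }, numeric(1))
  tab <- data.frame(candidate = candidates, mean_kl = mean_kl)
  best <- max(candidates[mean_kl == min(mean_kl)])
  list(n_thr = best, table = tab)
}

#' Augmentation quality report
#'
#' Per-group generator and counts plus the dataset-level per-feature KL
#' divergence between original and synthetic records.
#'
#' @param augmented output of [augment_dataset()].
#' @param features continuous columns to compare.
#' @return list with `groups` (data.frame), `kl_per_feature`, `kl_mean`.
#' @export
augmentation_report <- function(augmented,
                                features = c(TRAIT_COLUMNS, TARGET_COLUMNS)) {
  info <- attr(augmented, "augmentation")
  if (is.null(info)) stop("not an augment_dataset() result", call. = FALSE)
  groups <- do.call(rbind, lapply(info, function(i) {
    data.frame(
      group = i$key, generator = i$generator, n_orig = i$n_orig,
      n_synth = i$n_synth, stringsAsFactors = FALSE
    )
  }))
  rownames(groups) <- NULL
  kl <- feature_kl(
    augmented[!augmented$is_synthetic, , drop = FALSE],
    augmented[augmented$is_synthetic, , drop = FALSE],
    features = features
  )
  list(groups = groups, kl_per_feature = kl$per_feature, kl_mean = kl$mean)
}
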