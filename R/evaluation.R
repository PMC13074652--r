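#' Coefficient of determination and root mean squared error
#'
#' \eqn{R^2 = 1 - SSE/SST} with SST about `mean(y)`; an all-constant `y`
#' (SST = 0) is an error. \eqn{RMSE = \sqrt{\mathrm{mean}((y-\hat y)^2)}}.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return scalar metric.
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R^2 undefined: y is constant (SST = 0)", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' @rdname r2
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0L)
  sqrt(mean((y - yhat)^2))
}

#' Build a repeated K-fold plan over original records
#'
#' Seeded, shuffled K-fold assignment per repeat, near-stratified by
#' (season, treatment): records are ordered by stratum (shuffled within,
#' with a random cyclic offset) and dealt cyclically into folds, so fold
#' sizes differ by at most one and strata are spread across folds. Synthetic
#' rows are rejected — test folds must consist exclusively of original data.
#'
#' @param records original plant records.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @param stratify_by stratification columns (set `NULL` for a plain
#'   shuffle).
#' @return object of class `fold_plan`: `k`, `repeats`, `n`, `seed`, and an
#'   `n x repeats` integer matrix `assignments` of test-fold ids.
#' @export
make_fold_plan <- function(records, k = 5L, repeats = 3L, seed = 1L,
                           stratify_by = c("season", "treatment")) {
  if (any(records$is_synthetic)) {
    stop("fold plans are defined over original records only; filter synthetic rows first",
         call. = FALSE)
  }
  k <- as.integer(k)
  repeats <- as.integer(repeats)
  n <- nrow(records)
  if (n < k) stop(sprintf("need at least k = %d records, got %d", k, n), call. = FALSE)
  strata <- if (is.null(stratify_by)) {
    rep("all", n)
  } else {
    do.call(paste, c(records[stratify_by], sep = "|"))
  }
  assignments <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      ord <- unlist(lapply(split(seq_len(n), strata), sample), use.names = FALSE)
      offset <- sample.int(k, 1L)
      fold <- integer(n)
      fold[ord] <- ((seq_len(n) - 1L + offset) %% k) + 1L
      fold
    }, integer(n))
  })
  structure(
    list(k = as.integer(k), repeats = as.integer(repeats), n = n,
         seed = as.integer(seed), assignments = assignments),
    class = "fold_plan"
  )
}

#' Serialize / deserialize a fold plan as JSON
#'
#' @param plan a `fold_plan`.
#' @param path optional file path; with `NULL` the JSON string is returned.
#' @return `fold_plan_to_json()` returns the JSON string (or writes it);
#'   `fold_plan_from_json()` returns the `fold_plan`.
#' @export
fold_plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  js <- jsonlite::toJSON(
    list(
      k = plan$k, repeats = plan$repeats, n = plan$n, seed = plan$seed,
      assignments = plan$assignments
    ),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname fold_plan_to_json
#' @param json JSON string or file path to parse.
#' @export
fold_plan_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(
    list(k = as.integer(x$k), repeats = as.integer(x$repeats), n = as.integer(x$n),
         seed = as.integer(x$seed),
         assignments = matrix(as.integer(x$assignments), nrow = x$n)),
    class = "fold_plan"
  )
}

#' Precompute per-fold augmentation for a fold plan
#'
#' For every repeat and fold, regenerates the augmentation from that fold's
#' training originals only (the leakage-safe default), so several [run_cv()]
#' calls (e.g. both targets, or ablation variants) can share the work.
#'
#' @param records original records covered by `plan`.
#' @param plan a [make_fold_plan()].
#' @param config an [augmentation_config()]; the per-fold seed is derived
#'   from `config$seed`, the repeat and the fold.
#' @return nested list `cache[[repeat]][[fold]]`, each element the synthetic
#'   rows with attribute `source_idx` (indices into `records`).
#' @export
make_aug_cache <- function(records, plan, config = augmentation_config()) {
  stopifnot(inherits(plan, "fold_plan"), nrow(records) == plan$n)
  lapply(seq_len(plan$repeats), function(r) {
    lapply(seq_len(plan$k), function(f) {
      train <- which(plan$assignments[, r] != f)
      cfg <- config
      cfg$seed <- group_seed(config$seed, sprintf("rep%d-fold%d", r, f))
      aug <- augment_dataset(records[train, , drop = FALSE], cfg)
      info <- attr(aug, "augmentation")
      synth <- aug[aug$is_synthetic, , drop = FALSE]
      # map group-local source indices back to rows of `records`
      src <- unlist(lapply(info, function(i) train[i$source_idx]), use.names = FALSE)
      attr(synth, "source_idx") <- unique(src)
      synth
    })
  })
}

#' Leakage-safe repeated K-fold cross-validation
#'
#' For each repeat and fold: the training set is the fold's original
#' training records plus (if enabled) synthetic records freshly generated
#' from those training records only; models are fitted and test-fold
#' predictions collected into out-of-fold (OOF) vectors; R^2 and RMSE are
#' computed per repeat. Two leakage assertions run on every fold: test folds
#' contain zero synthetic rows, and every synthetic training row's source
#' records lie in that fold's training originals. If `"ensemble"` is among
#' `models`, simplex weights are fitted per repeat on the base learners' OOF
#' predictions by greedy selection.
#'
#' @param records original plant records.
#' @param target `"shoot_fw"` or `"fruit_fw"`.
#' @param plan a [make_fold_plan()] over `records`.
#' @param models model kinds: any of the base learners plus `"ensemble"`.
#' @param augment an [augmentation_config()], or `NULL` for no augmentation.
#' @param aug_cache optional [make_aug_cache()] result to reuse.
#' @param drop_group optional feature group to exclude (ablation).
#' @param seed integer seed for model fitting.
#' @param ffnn an [ffnn_config()].
#' @return object of class `cv_result`: `metrics` (per model x repeat),
#'   `oof` (list of per-repeat OOF matrices), `weights` (per repeat, if the
#'   ensemble was requested), `target`, `leakage_checked`.
#' @export
run_cv <- function(records, target = c("shoot_fw", "fruit_fw"), plan,
                   models = c(BASE_LEARNERS, "ensemble"), augment = NULL,
                   aug_cache = NULL, drop_group = NULL, seed = 1L,
                   ffnn = ffnn_config()) {
  target <- match.arg(target)
  stopifnot(inherits(plan, "fold_plan"))
  if (nrow(records) != plan$n) stop("fold plan does not match the records", call. = FALSE)
  if (any(records$is_synthetic)) stop("run_cv expects original records", call. = FALSE)
  base_kinds <- intersect(models, BASE_LEARNERS)
  want_ensemble <- "ensemble" %in% models
  if (want_ensemble && !length(base_kinds)) {
    stop("the ensemble needs at least one base learner", call. = FALSE)
  }
  if (!is.null(augment) && is.null(aug_cache)) {
    aug_cache <- make_aug_cache(records, plan, augment)
  }
  y <- records[[target]]
  metrics <- list()
  oof_list <- list()
  weights_list <- list()
  for (r in seq_len(plan$repeats)) {
    folds <- plan$assignments[, r]
    oof <- matrix(NA_real_, plan$n, length(base_kinds),
                  dimnames = list(NULL, base_kinds))
    for (f in seq_len(plan$k)) {
      test <- which(folds == f)
      train <- which(folds != f)
      train_df <- records[train, , drop = FALSE]
      # leakage assertion (a): test folds are original-only by construction
      stopifnot(!any(records$is_synthetic[test]))
      if (!is.null(aug_cache)) {
        synth <- aug_cache[[r]][[f]]
        # leakage assertion (b): synthetic sources within training originals
        src <- attr(synth, "source_idx")
        if (length(src) && !all(src %in% train)) {
          stop(sprintf(
            "leakage: synthetic rows in repeat %d fold %d derive from test records", r, f
          ), call. = FALSE)
        }
        train_df <- rbind(train_df, synth[, RECORD_COLUMNS], make.row.names = FALSE)
      }
      X_tr <- build_features(train_df, drop_group = drop_group)
      y_tr <- train_df[[target]]
      X_te <- build_features(records[test, , drop = FALSE], drop_group = drop_group)
      # FFNN early-stopping split: held-out original training rows only
      val <- NULL
      if ("ffnn" %in% base_kinds) {
        n_orig <- length(train)
        val_take <- with_seed(group_seed(seed, sprintf("val%d-%d", r, f)), {
          sample(n_orig, max(1L, floor(0.2 * n_orig)))
        })
        val <- list(idx = val_take)
      }
      for (kind in base_kinds) {
        fit_seed <- group_seed(seed, sprintf("%s-rep%d-fold%d", kind, r, f))
        fitted <- if (kind == "ffnn") {
          keep <- setdiff(seq_len(nrow(X_tr)), val$idx)
          train_base(kind, X_tr[keep, , drop = FALSE], y_tr[keep],
                     X_val = X_tr[val$idx, , drop = FALSE], y_val = y_tr[val$idx],
                     seed = fit_seed, ffnn = ffnn)
        } else {
          train_base(kind, X_tr, y_tr, seed = fit_seed)
        }
        oof[test, kind] <- predict(fitted, X_te)
      }
    }
    for (kind in base_kinds) {
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = kind, rep = r, r2 = r2(y, oof[, kind]), rmse = rmse(y, oof[, kind]),
        stringsAsFactors = FALSE
      )
    }
    if (want_ensemble) {
      wfit <- fit_ensemble_weights(oof, y)
      ens_pred <- drop(oof %*% wfit$weights)
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = "ensemble", rep = r, r2 = r2(y, ens_pred), rmse = rmse(y, ens_pred),
        stringsAsFactors = FALSE
      )
      weights_list[[r]] <- wfit$weights
      oof <- cbind(oof, ensemble = ens_pred)
    }
    oof_list[[r]] <- oof
  }
  structure(
    list(
      target = target, metrics = do.call(rbind, metrics), oof = oof_list,
      weights = weights_list, augmented = !is.null(aug_cache),
      drop_group = drop_group, leakage_checked = TRUE
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validation for %s (%s)\n", x$target,
    if (x$augmented) "augmented training folds" else "original data"
  ))
  print(summarize_metrics(x$metrics), row.names = FALSE)
  invisible(x)
}
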