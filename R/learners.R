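#' Feature taxonomy for the machine-learning models
#'
#' The model inputs fall into four named groups: basic traits (plant height,
#' basal stem diameter), structural traits (the per-stem diameters and
#' segment lengths), the temporal factor (DAT), and management factors
#' (interlighting treatment, pruning status). The two fresh-weight targets
#' are excluded.
#'
#' @return named list of column groups.
#' @export
feature_spec <- function() {
  list(
    basic = c("plant_height", "basal_stem_diam"),
    structural = c(
      "main_stem_diam", "left_stem_diam", "right_stem_diam",
      "main_stem_len", "left_stem_len", "right_stem_len"
    ),
    temporal = "dat",
    management = c("treatment", "pruning")
  )
}

# One-hot columns generated for the treatment factor.
treatment_onehot_cols <- function() paste0("treatment_", TREATMENT_LEVELS)

#' Build the numeric model matrix from plant records
#'
#' One-hot encodes the interlighting treatment, keeps pruning as 0/1, and
#' optionally drops a named feature group (for ablation).
#'
#' @param records plant-record data.frame.
#' @param drop_group optional feature-group name to exclude (see
#'   [feature_spec()]).
#' @return numeric matrix with named columns.
#' @export
build_features <- function(records, drop_group = NULL) {
  spec <- feature_spec()
  if (!is.null(drop_group)) {
    if (!drop_group %in% names(spec)) {
      stop(sprintf("unknown feature group '%s'", drop_group), call. = FALSE)
    }
    spec[[drop_group]] <- NULL
    if (!length(spec)) stop("removing this group leaves zero features", call. = FALSE)
  }
  cols <- list()
  for (grp in names(spec)) {
    for (f in spec[[grp]]) {
      if (f == "treatment") {
        for (lv in TREATMENT_LEVELS) {
          cols[[paste0("treatment_", lv)]] <- as.numeric(records$treatment == lv)
        }
      } else {
        cols[[f]] <- as.numeric(records[[f]])
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  X
}

BASE_LEARNERS <- c("gbm_depth", "gbm_leaf", "rf", "ffnn")

#' Train a single base regressor
#'
#' The base-learner roster mirrors the study's four-learner ensemble: two
#' gradient-boosted tree variants with different leaf-growth policies
#' (`"gbm_depth"`: depthwise; `"gbm_leaf"`: leaf-wise with a leaf cap), a
#' random forest (`"rf"`), and the feed-forward network (`"ffnn"`). Tree
#' hyperparameters are fixed documented defaults sized for a few thousand
#' training rows; no tuning loop. Deterministic given `seed`.
#'
#' @param kind one of `"gbm_depth"`, `"gbm_leaf"`, `"rf"`, `"ffnn"`.
#' @param X numeric feature matrix.
#' @param y numeric target.
#' @param X_val,y_val validation split for FFNN early stopping (original
#'   records only); ignored by the tree learners.
#' @param seed integer seed.
#' @param ffnn an [ffnn_config()].
#' @return an object of class `pepper_learner` exposing `predict()`.
#' @export
train_base <- function(kind, X, y, X_val = NULL, y_val = NULL, seed = 1L,
                       ffnn = ffnn_config()) {
  kind <- match.arg(kind, BASE_LEARNERS)
  X <- as.matrix(X)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  if (nrow(X) != length(y)) stop("y length does not match X rows", call. = FALSE)
  model <- switch(kind,
    gbm_depth = xgboost::xgboost(
      x = X, y = y, objective = "reg:squarederror", nrounds = 150L,
      learning_rate = 0.08, max_depth = 5L, min_child_weight = 2,
      tree_method = "hist",
      subsample = 0.9, colsample_bytree = 0.9, base_score = mean(y),
      nthreads = 1L, seed = seed, verbosity = 0L
    ),
    gbm_leaf = xgboost::xgboost(
      x = X, y = y, objective = "reg:squarederror", nrounds = 150L,
      learning_rate = 0.08, grow_policy = "lossguide", max_leaves = 31L,
      max_depth = 0L, tree_method = "hist", min_child_weight = 2,
      subsample = 0.9, colsample_bytree = 0.9, base_score = mean(y),
      nthreads = 1L, seed = seed, verbosity = 0L
    ),
    rf = ranger::ranger(
      x = X, y = y, num.trees = 200L, seed = seed, num.threads = 1L
    ),
    ffnn = train_ffnn(X, y, X_val = X_val, y_val = y_val, config = ffnn, seed = seed)
  )
  structure(
    list(kind = kind, model = model, features = colnames(X)),
    class = "pepper_learner"
  )
}

#' @export
predict.pepper_learner <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  switch(object$kind,
    gbm_depth = ,
    gbm_leaf = stats::predict(object$model, X),
    rf = stats::predict(object$model, data = X, num.threads = 1L)$predictions,
    ffnn = stats::predict(object$model, X)
  )
}

#' Fit simplex-constrained ensemble weights by greedy selection
#'
#' Greedy ensemble selection with replacement: starting from an empty
#' ensemble, each of `rounds` rounds adds the base model whose inclusion
#' minimizes the RMSE of the running average of out-of-fold predictions
#' (ties broken by column order). The returned weights are the selection
#' frequencies at the best-scoring round, so they are non-negative, sum to
#' one, and the weighted ensemble's OOF RMSE never exceeds the best single
#' base model's.
#'
#' @param oof numeric matrix of out-of-fold predictions, one column per base
#'   learner (named).
#' @param y observed target vector.
#' @param rounds number of greedy rounds.
#' @return list with `weights` (named, simplex), `ensemble_rmse`,
#'   `base_rmse`, and the per-round `rmse_trace`.
#' @export
fit_ensemble_weights <- function(oof, y, rounds = 100L) {
  oof <- as.matrix(oof)
  m <- ncol(oof)
  if (m < 1L) stop("need at least one base learner", call. = FALSE)
  if (nrow(oof) != length(y)) stop("OOF predictions not aligned with y", call. = FALSE)
  if (is.null(colnames(oof))) colnames(oof) <- paste0("base", seq_len(m))
  counts <- integer(m)
  run_sum <- numeric(length(y))
  trace <- numeric(rounds)
  best <- list(rmse = Inf, counts = counts, size = 0L)
  for (r in seq_len(rounds)) {
    cand_rmse <- vapply(seq_len(m), function(j) {
      sqrt(mean(((run_sum + oof[, j]) / r - y)^2))
    }, numeric(1))
    j <- which.min(cand_rmse)
    counts[j] <- counts[j] + 1L
    run_sum <- run_sum + oof[, j]
    trace[r] <- cand_rmse[j]
    if (cand_rmse[j] < best$rmse) best <- list(rmse = cand_rmse[j], counts = counts, size = r)
  }
  w <- best$counts / best$size
  names(w) <- colnames(oof)
  base_rmse <- vapply(seq_len(m), function(j) sqrt(mean((oof[, j] - y)^2)), numeric(1))
  names(base_rmse) <- colnames(oof)
  list(
    weights = w, ensemble_rmse = best$rmse, base_rmse = base_rmse,
    rmse_trace = trace
  )
}

#' Fit the full weighted ensemble on a record table
#'
#' Obtains out-of-fold predictions for the four base learners under an
#' internal K-fold split, fits the simplex weights by greedy selection, then
#' refits every base learner on all rows. Intended for interpretation
#' (ablation / Shapley) on a final model; cross-validated performance
#' figures come from [run_cv()] instead.
#'
#' @param records plant records (originals plus optional synthetic rows; the
#'   internal weight-fitting folds use original rows only as validation).
#' @param target `"shoot_fw"` or `"fruit_fw"`.
#' @param drop_group optional feature group to exclude.
#' @param k internal folds for weight fitting.
#' @param seed integer seed.
#' @param ffnn an [ffnn_config()].
#' @return object of class `pepper_ensemble` with `base` (fitted learners),
#'   `weights` and the feature names.
#' @export
fit_ensemble <- function(records, target = c("shoot_fw", "fruit_fw"),
                         drop_group = NULL, k = 5L, seed = 1L,
                         ffnn = ffnn_config()) {
  target <- match.arg(target)
  X <- build_features(records, drop_group = drop_group)
  y <- records[[target]]
  orig <- which(!records$is_synthetic)
  if (!length(orig)) stop("need original records to fit ensemble weights", call. = FALSE)
  folds <- with_seed(group_seed(seed, "ensemble-folds"), {
    sample(rep_len(seq_len(k), length(orig)))
  })
  oof <- matrix(NA_real_, length(orig), length(BASE_LEARNERS),
                dimnames = list(NULL, BASE_LEARNERS))
  for (f in seq_len(k)) {
    test_o <- orig[folds == f]
    train_rows <- setdiff(seq_len(nrow(records)), test_o)
    val_o <- intersect(train_rows, orig)
    for (kind in BASE_LEARNERS) {
      fitted <- train_base(
        kind, X[train_rows, , drop = FALSE], y[train_rows],
        seed = group_seed(seed, paste(kind, f)), ffnn = ffnn
      )
      oof[folds == f, kind] <- predict(fitted, X[test_o, , drop = FALSE])
    }
  }
  wfit <- fit_ensemble_weights(oof, y[orig])
  base <- lapply(stats::setNames(BASE_LEARNERS, BASE_LEARNERS), function(kind) {
    train_base(kind, X, y, seed = group_seed(seed, paste(kind, "final")), ffnn = ffnn)
  })
  structure(
    list(
      base = base, weights = wfit$weights, oof_rmse = wfit$base_rmse,
      ensemble_oof_rmse = wfit$ensemble_rmse, target = target,
      features = colnames(X), drop_group = drop_group
    ),
    class = "pepper_ensemble"
  )
}

#' Predict with a weighted ensemble
#'
#' \eqn{\hat y = \sum_i w_i\, \mathrm{base}_i(X)}: a convex combination, so
#' every prediction lies within the pointwise range of the base predictions.
#'
#' @param model a `pepper_ensemble`, or a list of fitted base learners.
#' @param X feature matrix.
#' @param weights simplex weight vector (taken from the model if omitted).
#' @return numeric prediction vector.
#' @export
predict_ensemble <- function(model, X, weights = NULL) {
  if (inherits(model, "pepper_ensemble")) {
    base <- model$base
    weights <- weights %||% model$weights
  } else {
    base <- model
    if (is.null(weights)) stop("weights required for a bare base-learner list", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  n <- nrow(as.matrix(X))
  preds <- vapply(base[names(weights)], function(b) predict(b, X), numeric(n))
  preds <- matrix(preds, nrow = n)
  drop(preds %*% weights)
}

#' @export
predict.pepper_ensemble <- function(object, X, ...) predict_ensemble(object, X)
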