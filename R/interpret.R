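#' Feature-group ablation under the shared fold plan
#'
#' Retrains the ensemble without one named feature group under the identical
#' fold plan and augmentation setting and reports the drop in out-of-fold
#' R^2 (mean over repeats) relative to the full model. A negative delta
#' (removal helps) is legitimate and reported as-is.
#'
#' @param records original plant records.
#' @param group_name one of the [feature_spec()] group names.
#' @param target `"shoot_fw"` or `"fruit_fw"`.
#' @param plan a [make_fold_plan()].
#' @param augment an [augmentation_config()] or `NULL`.
#' @param aug_cache optional shared [make_aug_cache()].
#' @param r2_full optional precomputed full-model R^2 (mean over repeats);
#'   computed when omitted.
#' @param seed integer seed.
#' @param models model set (the ensemble plus its bases by default).
#' @return one-row data.frame: `group`, `target`, `r2_full`, `r2_reduced`,
#'   `delta_r2`.
#' @export
ablate_group <- function(records, group_name, target, plan, augment = NULL,
                         aug_cache = NULL, r2_full = NULL, seed = 1L,
                         models = c(BASE_LEARNERS, "ensemble")) {
  if (!group_name %in% names(feature_spec())) {
    stop(sprintf("unknown feature group '%s'", group_name), call. = FALSE)
  }
  ens_r2 <- function(cv) mean(cv$metrics$r2[cv$metrics$model == "ensemble"])
  if (is.null(r2_full)) {
    full <- run_cv(records, target, plan, models = models, augment = augment,
                   aug_cache = aug_cache, seed = seed)
    r2_full <- ens_r2(full)
  }
  red <- run_cv(records, target, plan, models = models, augment = augment,
                aug_cache = aug_cache, drop_group = group_name, seed = seed)
  data.frame(
    group = group_name, target = target, r2_full = r2_full,
    r2_reduced = ens_r2(red), delta_r2 = r2_full - ens_r2(red),
    stringsAsFactors = FALSE
  )
}

#' Full ablation table over all feature groups
#'
#' @param records original plant records.
#' @param targets target columns.
#' @param plan a [make_fold_plan()].
#' @param augment an [augmentation_config()] or `NULL`.
#' @param aug_cache optional shared [make_aug_cache()] (built once here when
#'   augmentation is enabled and no cache is given).
#' @param seed integer seed.
#' @return data.frame with one row per group x target.
#' @export
ablation_table <- function(records, targets = TARGET_COLUMNS, plan,
                           augment = NULL, aug_cache = NULL, seed = 1L) {
  if (!is.null(augment) && is.null(aug_cache)) {
    aug_cache <- make_aug_cache(records, plan, augment)
  }
  out <- list()
  for (tg in targets) {
    full <- run_cv(records, tg, plan, augment = augment, aug_cache = aug_cache,
                   seed = seed)
    r2_full <- mean(full$metrics$r2[full$metrics$model == "ensemble"])
    for (grp in names(feature_spec())) {
      out[[length(out) + 1L]] <- ablate_group(
        records, grp, tg, plan, augment = augment, aug_cache = aug_cache,
        r2_full = r2_full, seed = seed
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Value function v(S) for one observation: mean prediction over the
# background rows with the features in S replaced by the observation's
# values. Implemented by batching all composite rows into one predict call.
shap_value_fun <- function(predict_fun, x, background, subsets) {
  n_bg <- nrow(background)
  big <- background[rep(seq_len(n_bg), length(subsets)), , drop = FALSE]
  for (si in seq_along(subsets)) {
    S <- subsets[[si]]
    if (!length(S)) next
    rows <- (si - 1L) * n_bg + seq_len(n_bg)
    big[rows, S] <- matrix(x[S], n_bg, length(S), byrow = TRUE)
  }
  preds <- predict_fun(big)
  vapply(seq_along(subsets), function(si) {
    mean(preds[(si - 1L) * n_bg + seq_len(n_bg)])
  }, numeric(1))
}

#' Permutation-sampling Shapley attribution
#'
#' Model-agnostic Shapley values with an interventional value function: for
#' a feature subset S, \eqn{v(S)} is the mean prediction over the background
#' rows with the features in S set to the explained observation's values.
#' In sampling mode, attributions average the marginal contributions along
#' `n_permutations` seeded random feature orderings per observation; with
#' `exact = TRUE` (feasible up to ~12 features) all \eqn{2^d} subsets are
#' enumerated and combined with the exact Shapley weights. Either estimator
#' satisfies efficiency: baseline + sum of attributions equals the model
#' prediction (up to the shared background average), exactly for the
#' telescoping permutation form.
#'
#' @param model a fitted model with a `predict` method, or a function
#'   `f(X) -> numeric`.
#' @param X_explain matrix/data.frame of observations to explain.
#' @param X_background background matrix (non-empty).
#' @param n_permutations sampled orderings per observation.
#' @param seed integer seed.
#' @param exact enumerate all subsets instead of sampling.
#' @return object of class `shap_result`: `attributions` (matrix obs x
#'   feature, in g of FW), `baseline` (mean background prediction),
#'   `prediction` (model predictions for `X_explain`), `feature_values`,
#'   and the estimator `settings`.
#' @export
shapley_attribution <- function(model, X_explain, X_background,
                                n_permutations = 200L, seed = 1L,
                                exact = FALSE) {
  predict_fun <- if (is.function(model)) model else function(X) predict(model, X)
  X_explain <- as.matrix(X_explain)
  X_background <- as.matrix(X_background)
  if (!nrow(X_background)) stop("background must be non-empty", call. = FALSE)
  if (!exact && n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  d <- ncol(X_explain)
  feat <- colnames(X_explain) %||% paste0("x", seq_len(d))
  baseline <- mean(predict_fun(X_background))
  pred <- predict_fun(X_explain)
  attr_mat <- matrix(0, nrow(X_explain), d, dimnames = list(NULL, feat))

  if (exact) {
    if (d > 12L) stop("exact enumeration is limited to 12 features", call. = FALSE)
    subsets <- lapply(0:(2^d - 1L), function(mask) which(bitwAnd(mask, 2^(0:(d - 1L))) > 0))
    sizes <- lengths(subsets)
    v_weights <- lapply(seq_len(d), function(j) {
      # Shapley kernel: w(S) = |S|!(d-|S|-1)!/d! for subsets excluding j
      has_j <- vapply(subsets, function(S) j %in% S, logical(1))
      w <- numeric(length(subsets))
      w[!has_j] <- factorial(sizes[!has_j]) * factorial(d - sizes[!has_j] - 1) / factorial(d)
      w
    })
    for (i in seq_len(nrow(X_explain))) {
      v <- shap_value_fun(predict_fun, X_explain[i, ], X_background, subsets)
      # index of S + {j}: add bit j
      masks <- 0:(2^d - 1L)
      for (j in seq_len(d)) {
        no_j <- bitwAnd(masks, 2^(j - 1L)) == 0
        with_j_idx <- masks[no_j] + 2^(j - 1L) + 1L
        attr_mat[i, j] <- sum(v_weights[[j]][no_j] * (v[with_j_idx] - v[no_j]))
      }
    }
  } else {
    with_seed(seed, {
      for (i in seq_len(nrow(X_explain))) {
        acc <- numeric(d)
        for (p in seq_len(n_permutations)) {
          ord <- sample.int(d)
          # prefix subsets along the ordering: v(empty), v({o1}), ...
          subsets <- c(list(integer(0)), lapply(seq_len(d), function(t) ord[seq_len(t)]))
          v <- shap_value_fun(predict_fun, X_explain[i, ], X_background, subsets)
          acc[ord] <- acc[ord] + diff(v)
        }
        attr_mat[i, ] <- acc / n_permutations
      }
    })
  }
  structure(
    list(
      attributions = attr_mat, baseline = baseline, prediction = pred,
      feature_values = X_explain,
      settings = list(
        n_background = nrow(X_background),
        n_permutations = if (exact) NA_integer_ else n_permutations,
        exact = exact, seed = seed
      )
    ),
    class = "shap_result"
  )
}

#' Summarize Shapley attributions for ranking
#'
#' Mean absolute attribution per feature, with the treatment one-hot columns
#' summed back into a single `treatment` factor.
#'
#' @param shap a [shapley_attribution()] result.
#' @param collapse_treatment sum the `treatment_*` one-hot columns.
#' @return named numeric vector sorted decreasing.
#' @export
shap_summary <- function(shap, collapse_treatment = TRUE) {
  a <- shap$attributions
  if (collapse_treatment) {
    oh <- intersect(colnames(a), treatment_onehot_cols())
    if (length(oh) > 1L) {
      tr <- rowSums(a[, oh, drop = FALSE])
      a <- cbind(a[, setdiff(colnames(a), oh), drop = FALSE], treatment = tr)
    }
  }
  sort(colMeans(abs(a)), decreasing = TRUE)
}

#' Combined importance report
#'
#' Machine-readable summary of the ablation and Shapley analyses: per-group
#' delta-R^2 bar data per target, the mean-|attribution| feature ranking,
#' and a beeswarm-style per-point export (attribution + feature value). A
#' missing attribution input yields an ablation-only report with a flag.
#'
#' @param ablation an [ablation_table()] result.
#' @param attribution named list of [shapley_attribution()] results per
#'   target (or `NULL`).
#' @return list of class `importance_report` with elements `ablation`,
#'   `shap_ranking`, `beeswarm`, `has_attribution`.
#' @export
importance_report <- function(ablation, attribution = NULL) {
  stopifnot(is.data.frame(ablation))
  out <- list(ablation = ablation, has_attribution = !is.null(attribution) && length(attribution) > 0)
  if (out$has_attribution) {
    out$shap_ranking <- lapply(attribution, shap_summary)
    out$beeswarm <- lapply(attribution, function(s) {
      vals <- s$feature_values
      data.frame(
        obs = rep(seq_len(nrow(s$attributions)), ncol(s$attributions)),
        feature = rep(colnames(s$attributions), each = nrow(s$attributions)),
        attribution = as.vector(s$attributions),
        feature_value = as.vector(vals[, colnames(s$attributions)]),
        stringsAsFactors = FALSE
      )
    })
  } else {
    out$shap_ranking <- NULL
    out$beeswarm <- NULL
  }
  class(out) <- "importance_report"
  out
}
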