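#' Geometric stem-volume proxies
#'
#' Computes a whole-plant volume proxy from the three stem segments (main,
#' left, right), summed over segments:
#' \describe{
#'   \item{stick}{the summed segment lengths (cm) — a length proxy; with
#'     `stick_mode = "height"` the plant height is used instead.}
#'   \item{cylinder}{\eqn{\sum_s \pi r_s^2 L_s} (cm^3), each segment a
#'     cylinder with radius from its own diameter.}
#'   \item{truncated_cone}{\eqn{\sum_s (\pi L_s/3)(r_1^2 + r_1 r_2 + r_2^2)}
#'     (cm^3) with proximal-to-distal taper: the main segment tapers from the
#'     basal to the main diameter, the laterals from the main diameter to
#'     their own.}
#' }
#' Diameters are converted mm to cm before use.
#'
#' @param records plant-record data.frame.
#' @param geometry one of `"stick"`, `"cylinder"`, `"truncated_cone"`.
#' @param stick_mode `"segments"` (default, summed segment lengths) or
#'   `"height"` (plant height only); stick geometry only.
#' @return numeric vector of volumes (cm for stick, cm^3 otherwise).
#' @export
#' @examples
#' r <- generate_dataset(sim_config(seed = 1))
#' v <- plant_volume(r, "cylinder")
plant_volume <- function(records, geometry = c("stick", "cylinder", "truncated_cone"),
                         stick_mode = c("segments", "height")) {
  geometry <- match.arg(geometry)
  stick_mode <- match.arg(stick_mode)
  lens <- cbind(records$main_stem_len, records$left_stem_len, records$right_stem_len)
  if (any(lens < 0)) stop("segment lengths must be non-negative", call. = FALSE)
  if (geometry == "stick") {
    if (stick_mode == "height") return(records$plant_height)
    return(rowSums(lens))
  }
  diam_cm <- cbind(
    basal = records$basal_stem_diam, main = records$main_stem_diam,
    left = records$left_stem_diam, right = records$right_stem_diam
  ) / 10
  if (any(diam_cm <= 0)) stop("stem diameters must be strictly positive", call. = FALSE)
  r <- diam_cm / 2
  if (geometry == "cylinder") {
    v <- pi * (r[, "main"]^2 * lens[, 1] + r[, "left"]^2 * lens[, 2] + r[, "right"]^2 * lens[, 3])
    return(unname(v))
  }
  cone_seg <- function(r1, r2, L) (pi * L / 3) * (r1^2 + r1 * r2 + r2^2)
  unname(
    cone_seg(r[, "basal"], r[, "main"], lens[, 1]) +
      cone_seg(r[, "main"], r[, "left"], lens[, 2]) +
      cone_seg(r[, "main"], r[, "right"], lens[, 3])
  )
}

new_allometric_fit <- function(form, coef, sse, converged, fallback_used,
                               geometry = NA_character_) {
  structure(
    list(
      geometry = geometry, form = form, coef = coef, sse = sse,
      converged = converged, fallback_used = fallback_used
    ),
    class = "allometric_fit"
  )
}

#' Fit an allometric scaling model
#'
#' Fits fresh weight FW against a volume proxy V with either a linear law
#' \eqn{FW = \alpha V + \beta} (ordinary least squares) or a logistic sigmoid
#' \eqn{FW = L / (1 + e^{-k(V - V_0)})} (bounded Levenberg-Marquardt least
#' squares). `L` is the asymptotic maximum FW (g), `k` the rate per volume
#' unit and `V0` the inflection volume. If the sigmoid optimizer fails to
#' converge, or converges to a non-finite or non-positive `L`, the linear
#' model is refitted instead and `fallback_used` is set.
#'
#' Sigmoid initialization: \eqn{L_0 = 1.1 \max(FW)}, \eqn{V_0 =
#' \mathrm{median}(V)}, \eqn{k_0 = 4 / \mathrm{range}(V)}; bounds
#' \eqn{L \in (0, 10\max FW]}, \eqn{k > 0}, \eqn{V_0 \in [\min V, \max V]}.
#'
#' @param V numeric vector of volume proxies.
#' @param FW numeric vector of fresh weights (g).
#' @param form `"linear"` or `"sigmoid"`.
#' @param geometry optional geometry label carried in the fit object.
#' @param max_eval iteration cap for the sigmoid optimizer.
#' @return an object of class `allometric_fit` with elements `form`, `coef`
#'   (named `alpha`/`beta` or `L`/`k`/`V0`), `sse`, `converged`,
#'   `fallback_used`.
#' @export
fit_allometric <- function(V, FW, form = c("linear", "sigmoid"),
                           geometry = NA_character_, max_eval = 10000L) {
  form <- match.arg(form)
  stopifnot(length(V) == length(FW))
  keep <- is.finite(V) & is.finite(FW)
  V <- V[keep]; FW <- FW[keep]
  if (form == "linear") {
    return(fit_allometric_linear(V, FW, geometry))
  }
  if (length(V) < 4L) {
    stop("sigmoid fit needs at least 4 points (3 parameters)", call. = FALSE)
  }
  fit <- try_fit_sigmoid(V, FW, max_eval)
  if (is.null(fit)) {
    lin <- fit_allometric_linear(V, FW, geometry)
    lin$fallback_used <- TRUE
    return(lin)
  }
  fit$geometry <- geometry
  fit
}

fit_allometric_linear <- function(V, FW, geometry = NA_character_) {
  if (length(V) < 2L || length(unique(V)) < 2L) {
    stop("degenerate design: need at least 2 distinct V values", call. = FALSE)
  }
  m <- stats::lm(FW ~ V)
  cf <- stats::coef(m)
  new_allometric_fit(
    form = "linear",
    coef = c(alpha = unname(cf[["V"]]), beta = unname(cf[["(Intercept)"]])),
    sse = sum(stats::residuals(m)^2), converged = TRUE, fallback_used = FALSE,
    geometry = geometry
  )
}

try_fit_sigmoid <- function(V, FW, max_eval) {
  max_fw <- max(FW)
  if (!is.finite(max_fw) || max_fw <= 0) return(NULL)
  start <- list(L = 1.1 * max_fw, k = 4 / max(diff(range(V)), .Machine$double.eps),
                V0 = stats::median(V))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      FW ~ L / (1 + exp(-k * (V - V0))),
      start = start,
      lower = c(L = .Machine$double.eps, k = .Machine$double.eps, V0 = min(V)),
      upper = c(L = 10 * max_fw, k = Inf, V0 = max(V)),
      control = minpack.lm::nls.lm.control(
        maxiter = 1024L, maxfev = max_eval, ftol = 1e-10, ptol = 1e-12
      )
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  if (!conv || !all(is.finite(cf)) || cf[["L"]] <= 0) return(NULL)
  new_allometric_fit(
    form = "sigmoid",
    coef = c(L = unname(cf[["L"]]), k = unname(cf[["k"]]), V0 = unname(cf[["V0"]])),
    sse = sum(stats::residuals(fit)^2), converged = TRUE, fallback_used = FALSE
  )
}

#' Predict fresh weight from an allometric fit
#'
#' @param object an `allometric_fit`.
#' @param V numeric vector of volume proxies.
#' @param ... unused.
#' @return numeric vector of predicted FW (g); sigmoid predictions lie
#'   strictly in (0, L).
#' @export
predict.allometric_fit <- function(object, V, ...) {
  cf <- object$coef
  if (object$form == "linear") {
    cf[["alpha"]] * V + cf[["beta"]]
  } else {
    cf[["L"]] / (1 + exp(-cf[["k"]] * (V - cf[["V0"]])))
  }
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric %s fit%s: %s  (SSE %.4g%s)\n",
    x$form,
    if (!is.na(x$geometry)) paste0(" [", x$geometry, "]") else "",
    paste(sprintf("%s=%.4g", names(x$coef), x$coef), collapse = ", "),
    x$sse,
    if (x$fallback_used) ", linear fallback" else ""
  ))
  invisible(x)
}

#' Cross-validated evaluation of the allometric baselines
#'
#' Fits every geometry x functional-form combination per training fold of a
#' shared fold plan and scores out-of-fold predictions per repeat, for one or
#' both fresh-weight targets. Per-fold fit failures trigger the documented
#' linear fallback; fully failed fits are recorded, not raised.
#'
#' @param records original plant records (no synthetic rows).
#' @param plan a [make_fold_plan()] over `records`.
#' @param geometries volume proxies to evaluate.
#' @param forms functional forms to evaluate.
#' @param targets target columns.
#' @param stick_mode passed to [plant_volume()].
#' @return data.frame with columns `geometry`, `form`, `target`, `rep`,
#'   `r2`, `rmse`, `n_fallback`.
#' @export
evaluate_allometric <- function(records, plan,
                                geometries = c("stick", "cylinder", "truncated_cone"),
                                forms = c("linear", "sigmoid"),
                                targets = TARGET_COLUMNS,
                                stick_mode = "segments") {
  stopifnot(inherits(plan, "fold_plan"), nrow(records) == plan$n)
  out <- list()
  vols <- lapply(stats::setNames(geometries, geometries), function(g) {
    plant_volume(records, g, stick_mode = stick_mode)
  })
  for (g in geometries) {
    V <- vols[[g]]
    for (fo in forms) {
      for (tg in targets) {
        y <- records[[tg]]
        for (r in seq_len(plan$repeats)) {
          folds <- plan$assignments[, r]
          pred <- rep(NA_real_, plan$n)
          n_fb <- 0L
          for (f in seq_len(plan$k)) {
            test <- which(folds == f)
            train <- which(folds != f)
            fit <- tryCatch(
              fit_allometric(V[train], y[train], form = fo, geometry = g),
              error = function(e) NULL
            )
            if (is.null(fit)) next # recorded as missing predictions
            if (fit$fallback_used) n_fb <- n_fb + 1L
            pred[test] <- predict(fit, V[test])
          }
          ok <- !is.na(pred)
          out[[length(out) + 1L]] <- data.frame(
            geometry = g, form = fo, target = tg, rep = r,
            r2 = r2(y[ok], pred[ok]), rmse = rmse(y[ok], pred[ok]),
            n_fallback = n_fb, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Summarize a per-repeat metrics table
#'
#' Mean and standard deviation of R^2 and RMSE across cross-validation
#' repeats, per model configuration.
#'
#' @param metrics data.frame with a `rep` column plus `r2` and `rmse`.
#' @param by grouping columns (defaults to everything except `rep`, `r2`,
#'   `rmse`).
#' @return data.frame with `r2_mean`, `r2_sd`, `rmse_mean`, `rmse_sd`.
#' @export
summarize_metrics <- function(metrics, by = NULL) {
  if (is.null(by)) by <- setdiff(names(metrics), c("rep", "r2", "rmse", "n_fallback"))
  key <- interaction(metrics[by], drop = TRUE, lex.order = TRUE)
  parts <- split(metrics, key)
  res <- lapply(parts, function(p) {
    cbind(
      p[1L, by, drop = FALSE],
      data.frame(
        r2_mean = mean(p$r2), r2_sd = stats::sd(p$r2),
        rmse_mean = mean(p$rmse), rmse_sd = stats::sd(p$rmse)
      )
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
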