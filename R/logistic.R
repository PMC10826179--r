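#' Penalized logistic regression with elastic-net mixing
#'
#' Minimizes cross-entropy plus `(1/C) * [l1_ratio * L1 +
#' (1 - l1_ratio)/2 * L2]` over the coefficients, with `C` the inverse
#' regularization strength. Features are standardized to zero mean / unit
#' variance using the training statistics; predictions reuse them.
#' Backed by glmnet (`lambda = 1 / (C * n)`, `alpha = l1_ratio`).
#'
#' @param X Numeric matrix, samples x features (training data).
#' @param y Binary labels (0/1 or logical) aligned to rows of `X`.
#' @param inv_reg Inverse regularization strength C (> 0).
#' @param l1_ratio Elastic-net mixing in `[0, 1]` (0 = ridge, 1 = lasso).
#' @return An `elastic_logistic` model; `predict()` returns probabilities
#'   of the positive class.
#' @export
fit_elastic_logistic <- function(X, y, inv_reg, l1_ratio) {
  assert_scalar_num(inv_reg, "inv_reg", lo = .Machine$double.xmin)
  assert_scalar_num(l1_ratio, "l1_ratio", 0, 1)
  y <- as.integer(y)
  if (!all(y %in% 0:1) || length(unique(y)) < 2L) stop_mp("`y` must contain both 0 and 1")
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  lambda <- 1 / (inv_reg * nrow(X))
  fit <- glmnet_binomial(Xs, y, alpha = l1_ratio, lambdas = lambda)
  structure(
    list(center = std$center, scale = std$scale,
         intercept = fit$a0[1], beta = fit$beta[, 1],
         inv_reg = inv_reg, l1_ratio = l1_ratio, lambda = lambda,
         features = colnames(X)),
    class = "elastic_logistic"
  )
}

#' @export
predict.elastic_logistic <- function(object, newx, ...) {
  if (!is.null(object$features)) newx <- newx[, object$features, drop = FALSE]
  Xs <- standardize_apply(newx, list(center = object$center, scale = object$scale))
  eta <- drop(Xs %*% object$beta) + object$intercept
  stats::plogis(eta)
}

#' @export
print.elastic_logistic <- function(x, ...) {
  cat(sprintf("<elastic_logistic> %d features (%d nonzero), C = %g, l1_ratio = %g\n",
              length(x$beta), sum(x$beta != 0), x$inv_reg, x$l1_ratio))
  invisible(x)
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1   # constant columns pass through as 0
  list(center = center, scale = scale)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

# glmnet binomial fit at user-supplied lambda(s); pads a zero column when
# only one feature is selected (glmnet requires >= 2 columns) and strips it
# from the returned coefficients
glmnet_binomial <- function(Xs, y, alpha, lambdas) {
  padded <- FALSE
  if (ncol(Xs) < 2L) {
    Xs <- cbind(Xs, `.pad.` = 0)
    padded <- TRUE
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(Xs, factor(y, levels = 0:1), family = "binomial",
                   alpha = alpha, lambda = sort(lambdas, decreasing = TRUE),
                   standardize = FALSE),
    # glmnet nags about small classes on every inner-CV fold; nothing actionable
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  beta <- as.matrix(fit$beta)
  a0 <- fit$a0
  # map back to the requested lambda order
  pos <- match(round(sort(lambdas, decreasing = TRUE), 12), round(fit$lambda, 12))
  idx <- match(lambdas, sort(lambdas, decreasing = TRUE))
  keep <- pos[idx]
  if (anyNA(keep)) { # glmnet dropped lambdas (rare); fall back to nearest
    keep[is.na(keep)] <- vapply(lambdas[is.na(keep)], function(l) {
      which.min(abs(fit$lambda - l))
    }, 0L)
  }
  beta <- beta[, keep, drop = FALSE]
  a0 <- a0[keep]
  if (padded) beta <- beta[-nrow(beta), , drop = FALSE]
  list(beta = beta, a0 = a0)
}

#' Nested cross-validated elastic-net logistic classification
#'
#' Outer folds estimate performance; inner folds tune the grid. Inside
#' every inner training split the pipeline is refit from scratch:
#' univariate t-test feature ranking, training-statistics
#' standardization, and a glmnet elastic-net path over all C values, so no
#' validation sample ever informs selection or scaling. The combination
#' with the highest mean inner AUC wins (ties break toward smaller
#' feature percentage, then smaller C, then larger l1 ratio); it is refit
#' on the full outer-training split and scored on the held-out fold.
#'
#' @param nm A `normalized_matrix`.
#' @param ann A `sample_annotation`.
#' @param positive Class label(s) scored as the positive class.
#' @param negative Class label(s) forming the negative class.
#' @param grid An [lr_grid()].
#' @param spec A [cv_spec()] (10 inner / 5 outer folds by default).
#' @return A `model_result`: per-fold AUCs, mean AUC with 95% CI
#'   half-width (t distribution over the fold AUCs), best AUC, per-fold
#'   chosen hyperparameters and selected features, and pooled out-of-fold
#'   prediction scores covering every sample exactly once.
#' @export
nested_cv_logistic <- function(nm, ann, positive, negative = "RLN",
                               grid = lr_grid(), spec = cv_spec()) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(grid, "lr_grid"),
            inherits(spec, "cv_spec"))
  cls <- aligned_classes(ann, colnames(nm$values))
  use <- cls %in% c(positive, negative)
  X <- t(nm$values[, use, drop = FALSE])
  y <- as.integer(cls[use] %in% positive)
  ids <- rownames(X)
  if (sum(y == 1L) < spec$outer_folds || sum(y == 0L) < spec$outer_folds) {
    stop_mp("each class needs at least `outer_folds` samples")
  }
  combos <- enumerate_grid(grid)
  outer <- stratified_folds(y, spec$outer_folds, derive_seed(spec$seed, "outer"))

  fold_auc <- numeric(spec$outer_folds)
  fold_params <- vector("list", spec$outer_folds)
  fold_features <- vector("list", spec$outer_folds)
  pred <- data.frame(sample_id = ids, score = NA_real_, label = y,
                     fold = outer, stringsAsFactors = FALSE)

  for (f in seq_len(spec$outer_folds)) {
    tr <- which(outer != f); va <- which(outer == f)
    inner_auc <- tune_logistic(X[tr, , drop = FALSE], y[tr], grid, combos,
                               spec$inner_folds,
                               derive_seed(spec$seed, paste0("inner", f)))
    best <- combos[which.max(inner_auc), ]  # combos are in tie-break order
    sel <- rank_features(X[tr, , drop = FALSE], y[tr], best$pct)
    model <- fit_elastic_logistic(X[tr, sel, drop = FALSE], y[tr],
                                  best$inv_reg, best$l1_ratio)
    scores <- predict(model, X[va, , drop = FALSE])
    pred$score[va] <- scores
    fold_auc[f] <- auc(scores, y[va])
    fold_params[[f]] <- list(pct = best$pct, inv_reg = best$inv_reg,
                             l1_ratio = best$l1_ratio,
                             mean_inner_auc = max(inner_auc, na.rm = TRUE))
    fold_features[[f]] <- sel
  }
  model_result(fold_auc, fold_params, fold_features, pred,
               positive = positive, negative = negative,
               learner = "elastic_logistic")
}

# mean inner-CV AUC for every grid combination; shares feature ranking
# across percentages and glmnet paths across C values for speed
tune_logistic <- function(X, y, grid, combos, k, seed) {
  folds <- stratified_folds(y, k, seed)
  acc <- matrix(NA_real_, nrow = nrow(combos), ncol = k)
  pcts <- grid$feature_percentages
  alphas <- grid$l1_ratios
  cs <- grid$inv_regularization
  for (g in seq_len(k)) {
    it <- which(folds != g); iv <- which(folds == g)
    if (length(unique(y[iv])) < 2L || length(unique(y[it])) < 2L) next
    ranked <- rank_features(X[it, , drop = FALSE], y[it], 100)
    for (pct in pcts) {
      n_sel <- max(1L, round(pct / 100 * ncol(X)))
      sel <- ranked[seq_len(n_sel)]
      std <- standardize_fit(X[it, sel, drop = FALSE])
      Xs_it <- standardize_apply(X[it, sel, drop = FALSE], std)
      Xs_iv <- standardize_apply(X[iv, sel, drop = FALSE], std)
      lambdas <- 1 / (cs * length(it))
      for (al in alphas) {
        fit <- glmnet_binomial(Xs_it, y[it], alpha = al, lambdas = lambdas)
        eta <- sweep(Xs_iv %*% fit$beta, 2L, fit$a0, "+")
        for (ci in seq_along(cs)) {
          row <- which(combos$pct == pct & combos$inv_reg == cs[ci] &
                         combos$l1_ratio == al)
          acc[row, g] <- auc(eta[, ci], y[iv])
        }
      }
    }
  }
  rowMeans(acc, na.rm = TRUE)
}

#' Container for a nested-CV outcome
#'
#' @param fold_auc Numeric vector of outer-fold AUCs.
#' @param fold_params Per-fold chosen hyperparameters.
#' @param fold_features Per-fold selected feature ids.
#' @param predictions Data frame of pooled out-of-fold predictions
#'   (`sample_id`, `score`, `label`, `fold`).
#' @param positive,negative Class labels of the two arms.
#' @param learner Learner name.
#' @return A `model_result`.
#' @export
model_result <- function(fold_auc, fold_params, fold_features, predictions,
                         positive, negative, learner) {
  k <- length(fold_auc)
  stopifnot(all(fold_auc >= 0 & fold_auc <= 1), !anyNA(predictions$score))
  ci <- stats::qt(0.975, df = k - 1) * stats::sd(fold_auc) / sqrt(k)
  structure(
    list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
         ci_half_width = ci, best_auc = max(fold_auc),
         fold_params = fold_params, fold_features = fold_features,
         predictions = predictions,
         positive = positive, negative = negative, learner = learner),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s: %s vs %s\n", x$learner,
              paste(x$positive, collapse = "+"), paste(x$negative, collapse = "+")))
  cat(sprintf("  AUC %.3f +/- %.3f (95%% CI over %d outer folds), best fold %.3f\n",
              x$mean_auc, x$ci_half_width, length(x$fold_auc), x$best_auc))
  invisible(x)
}

#' @export
summary.model_result <- function(object, ...) {
  print(object)
  for (f in seq_along(object$fold_params)) {
    p <- object$fold_params[[f]]
    cat(sprintf("  fold %d: AUC %.3f | %s | %d features\n", f,
                object$fold_auc[f],
                paste(names(p), vapply(p, format, ""), sep = "=", collapse = ", "),
                length(object$fold_features[[f]])))
  }
  invisible(object)
}

#' Write a model result as JSON (plus a CSV of pooled predictions)
#'
#' @param res A `model_result`.
#' @param path JSON output path; predictions go to the same stem with
#'   `_predictions.csv` appended.
#' @return `path`, invisibly.
#' @export
write_model_result <- function(res, path) {
  stopifnot(inherits(res, "model_result"))
  payload <- res[c("fold_auc", "mean_auc", "ci_half_width", "best_auc",
                   "fold_params", "fold_features", "positive", "negative",
                   "learner")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  csv <- sub("\\.json$", "", path)
  utils::write.csv(res$predictions, paste0(csv, "_predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
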