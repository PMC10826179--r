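#' Permutation feature importance on held-out data
#'
#' Importance of a feature is the drop in a held-out metric when that
#' feature's column is shuffled: `baseline - mean(permuted metric)` over
#' `repeats` independent shuffles. A feature the model ignores scores
#' exactly zero. Metric: AUC for binary scores, accuracy for multi-class
#' predictions.
#'
#' @param score_fun Function mapping a samples x features matrix to
#'   numeric scores (binary) or a probability matrix / class labels
#'   (multi-class). Fitted `elastic_logistic` and `ranger` objects are
#'   also accepted directly.
#' @param X Held-out samples x features matrix.
#' @param y Held-out labels (binary for `metric = "auc"`).
#' @param metric `"auc"` or `"accuracy"`.
#' @param repeats Number of independent shuffles per feature (>= 2,
#'   default 20).
#' @param seed Integer seed; results are deterministic given it.
#' @return An `importance_table` data.frame (`feature`, `importance`,
#'   `sd`), sorted by decreasing importance.
#' @export
permutation_importance <- function(score_fun, X, y, metric = c("auc", "accuracy"),
                                   repeats = 20, seed = 1L) {
  metric <- match.arg(metric)
  if (repeats < 2L) stop_mp("`repeats` must be >= 2")
  score_fun <- as_score_fun(score_fun)
  measure <- if (metric == "auc") {
    function(out) auc(drop(out), y)
  } else {
    function(out) mean(as_class_labels(out) == as.character(y))
  }
  baseline <- measure(score_fun(X))
  feats <- colnames(X)
  imp <- matrix(NA_real_, nrow = length(feats), ncol = repeats,
                dimnames = list(feats, NULL))
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      perm <- sample.int(nrow(X))
      for (j in seq_along(feats)) {
        Xp <- X
        Xp[, j] <- X[perm, j]
        imp[j, r] <- baseline - measure(score_fun(Xp))
      }
    }
  })
  out <- data.frame(feature = feats, importance = rowMeans(imp),
                    sd = apply(imp, 1L, stats::sd),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"),
            baseline = baseline, metric = metric, repeats = repeats)
}

as_score_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "elastic_logistic")) {
    return(function(X) predict(model, X))
  }
  if (inherits(model, "ranger")) {
    return(function(X) predict_rf(model, X))
  }
  stop_mp("score_fun must be a function, elastic_logistic or ranger model")
}

as_class_labels <- function(out) {
  if (is.matrix(out)) colnames(out)[max.col(out, ties.method = "first")]
  else as.character(out)
}

#' @export
print.importance_table <- function(x, n = 10, ...) {
  cat(sprintf("<importance_table> %d features, metric %s (baseline %.3f), %d repeats\n",
              nrow(x), attr(x, "metric"), attr(x, "baseline"), attr(x, "repeats")))
  print.data.frame(utils::head(x, n), digits = 3)
  invisible(x)
}

#' Permutation importance aggregated over nested-CV outer folds
#'
#' Applies [permutation_importance()] to each outer fold's fitted forest
#' and its own held-out samples, then averages the per-fold importances.
#'
#' @param rf_result The list returned by [nested_cv_random_forest()].
#' @param nm The `normalized_matrix` the result was fit on.
#' @param ann The `sample_annotation`.
#' @param repeats Shuffles per feature per fold (default 10).
#' @param seed Integer seed.
#' @return An `importance_table` of fold-averaged importances.
#' @export
nested_rf_importance <- function(rf_result, nm, ann, repeats = 10, seed = 1L) {
  res <- rf_result$model
  if (is.null(res$fold_models)) stop_mp("result carries no fold models")
  cls <- aligned_classes(ann, colnames(nm$values))
  X <- t(nm$values)
  tabs <- lapply(seq_along(res$fold_models), function(f) {
    fm <- res$fold_models[[f]]
    permutation_importance(fm$fit, X[fm$validation, , drop = FALSE],
                           droplevels(cls[fm$validation]),
                           metric = "accuracy", repeats = repeats,
                           seed = derive_seed(seed, paste0("imp", f)))
  })
  feats <- tabs[[1]]$feature
  mat <- vapply(tabs, function(tb) tb$importance[match(feats, tb$feature)],
                numeric(length(feats)))
  out <- data.frame(feature = feats, importance = rowMeans(mat),
                    sd = apply(mat, 1L, stats::sd), stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"),
            baseline = mean(vapply(tabs, attr, 0, "baseline")),
            metric = "accuracy", repeats = repeats)
}

#' Common diagnostic panel across binary classifiers
#'
#' Per model, keep features selected in at least `min_fold_frequency` of
#' the outer folds; return the intersection across models — the stable
#' core panel shared by all comparisons.
#'
#' @param results List of >= 1 `model_result` objects.
#' @param min_fold_frequency Minimum fraction of outer folds a feature
#'   must be selected in (default 0.8).
#' @return Character vector of miRNA ids (possibly empty).
#' @export
common_panel <- function(results, min_fold_frequency = 0.8) {
  stopifnot(length(results) >= 1L)
  stable <- lapply(results, function(res) {
    k <- length(res$fold_features)
    tab <- table(unlist(res$fold_features, use.names = FALSE))
    names(tab)[tab >= min_fold_frequency * k]
  })
  sort(Reduce(intersect, stable))
}
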