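#' Nested cross-validated multi-class random forest
#'
#' Three-class forest over the full retained panel (no univariate
#' pre-filter). Inner folds pick the grid combination with the highest
#' mean one-vs-rest macro AUC; the winner is refit on the outer-training
#' split and its out-of-fold predictions are pooled over the outer folds
#' into a single confusion matrix in which every sample is predicted
#' exactly once.
#'
#' @param nm A `normalized_matrix`.
#' @param ann A `sample_annotation`.
#' @param grid An [rf_grid()].
#' @param spec A [cv_spec()]; the conventional layout is 3 inner / 5
#'   outer folds.
#' @return List with `model` (a `model_result` whose fold AUCs are macro
#'   one-vs-rest AUCs and whose predictions carry class probabilities)
#'   and `confusion` (a `confusion_matrix`).
#' @export
nested_cv_random_forest <- function(nm, ann, grid = rf_grid(),
                                    spec = cv_spec(inner_folds = 3)) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(grid, "rf_grid"),
            inherits(spec, "cv_spec"))
  cls <- aligned_classes(ann, colnames(nm$values))
  X <- t(nm$values)
  y <- droplevels(cls)
  ids <- rownames(X)
  if (any(table(y) < spec$outer_folds)) {
    stop_mp("each class needs at least `outer_folds` samples")
  }
  combos <- enumerate_grid(grid)
  outer <- stratified_folds(y, spec$outer_folds, derive_seed(spec$seed, "rf_outer"))

  levs <- levels(y)
  fold_auc <- numeric(spec$outer_folds)
  fold_params <- vector("list", spec$outer_folds)
  fold_features <- vector("list", spec$outer_folds)
  predicted <- factor(rep(levs[1], length(y)), levels = levs)
  prob <- matrix(NA_real_, nrow = length(y), ncol = length(levs),
                 dimnames = list(ids, levs))
  fold_models <- vector("list", spec$outer_folds)

  for (f in seq_len(spec$outer_folds)) {
    tr <- which(outer != f); va <- which(outer == f)
    inner <- stratified_folds(y[tr], spec$inner_folds,
                              derive_seed(spec$seed, paste0("rf_inner", f)))
    inner_auc <- matrix(NA_real_, nrow = nrow(combos), ncol = spec$inner_folds)
    for (g in seq_len(spec$inner_folds)) {
      it <- tr[inner != g]; iv <- tr[inner == g]
      if (length(unique(y[iv])) < 2L) next
      for (ci in seq_len(nrow(combos))) {
        fit <- fit_rf(X[it, , drop = FALSE], y[it], combos[ci, ], grid$n_trees,
                      derive_seed(spec$seed, sprintf("rf_fit_%d_%d_%d", f, g, ci)))
        pr <- predict_rf(fit, X[iv, , drop = FALSE])
        inner_auc[ci, g] <- macro_ovr_auc(pr, y[iv])
      }
    }
    best_i <- which.max(rowMeans(inner_auc, na.rm = TRUE))
    best <- combos[best_i, ]
    fit <- fit_rf(X[tr, , drop = FALSE], y[tr], best, grid$n_trees,
                  derive_seed(spec$seed, sprintf("rf_final_%d", f)))
    pr <- predict_rf(fit, X[va, , drop = FALSE])
    prob[va, ] <- pr
    predicted[va] <- factor(levs[max.col(pr, ties.method = "first")], levels = levs)
    fold_auc[f] <- macro_ovr_auc(pr, y[va])
    fold_params[[f]] <- as.list(best)
    fold_features[[f]] <- colnames(X)
    fold_models[[f]] <- list(fit = fit, validation = va)
  }
  pred <- data.frame(sample_id = ids, score = prob[cbind(seq_along(y), as.integer(y))],
                     label = as.character(y), predicted = as.character(predicted),
                     fold = outer, stringsAsFactors = FALSE)
  res <- model_result(fold_auc, fold_params, fold_features, pred,
                      positive = levs[-1], negative = levs[1],
                      learner = "random_forest")
  res$class_probabilities <- prob
  res$fold_models <- fold_models
  list(model = res, confusion = confusion_matrix(y, predicted))
}

# one ranger probability forest for a grid row
fit_rf <- function(X, y, combo, n_trees, seed) {
  p <- ncol(X)
  mtry <- switch(as.character(combo$max_features),
                 auto = , sqrt = max(1L, floor(sqrt(p))),
                 log2 = max(1L, floor(log2(p))),
                 none = p,
                 stop_mp("unknown max_features value"))
  ranger::ranger(
    x = X, y = y,
    num.trees = n_trees,
    mtry = mtry,
    max.depth = combo$max_depth,
    replace = combo$bootstrap,
    sample.fraction = 1,
    splitrule = "gini",
    probability = TRUE,
    seed = seed,
    num.threads = 1
  )
}

predict_rf <- function(fit, newx) {
  stats::predict(fit, data = newx, num.threads = 1)$predictions
}

# mean over classes of one-vs-rest AUC; classes absent from y are skipped
macro_ovr_auc <- function(prob, y) {
  levs <- colnames(prob)
  vals <- vapply(levs, function(cl) {
    lab <- as.integer(y == cl)
    if (length(unique(lab)) < 2L) return(NA_real_)
    auc(prob[, cl], lab)
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Three-class confusion matrix from pooled out-of-fold predictions
#'
#' @param actual Factor of true classes.
#' @param predicted Factor of predicted classes (same levels).
#' @return A `confusion_matrix`: `counts` (rows = actual, columns =
#'   predicted) and `fractions` (row-normalized).
#' @export
confusion_matrix <- function(actual, predicted) {
  counts <- table(actual = actual, predicted = predicted)
  fractions <- sweep(counts, 1L, pmax(rowSums(counts), 1L), "/")
  structure(list(counts = unclass(counts), fractions = unclass(fractions)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> counts (rows = actual):\n")
  print(x$counts)
  cat("row fractions:\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' @param cm A `confusion_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(cm, path) {
  df <- data.frame(actual = rownames(cm$counts), cm$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
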