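#' Rank-based (Mann-Whitney) AUC with tie correction
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted half, computed from midranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1, logical, or a 2-level factor whose
#'   second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_mp("labels must be binary")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_mp("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles within each class and deals samples to folds round-robin, so
#' class counts differ by at most one across folds and every sample lands
#' in exactly one fold. Deterministic given the seed.
#'
#' @param labels Class labels (any atomic/factor).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, aligned to `labels`.
#' @export
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2L || k > n) stop_mp("`k` must be in [2, n]")
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

#' Cross-validation layout
#'
#' @param outer_folds Outer evaluation folds (default 5).
#' @param inner_folds Inner tuning folds (default 10; 3 is conventional
#'   for the random forest).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Integer seed driving all fold assignments.
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(outer_folds = 5, inner_folds = 10, stratified = TRUE, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Elastic-net logistic regression tuning grid
#'
#' The default axes give 3 x 9 x 5 = 135 parameter combinations.
#'
#' @param feature_percentages Percent of available features kept by the
#'   univariate filter (default `c(5, 10, 20)`).
#' @param inv_regularization Inverse regularization strengths C (default
#'   `10^(-4:4)`).
#' @param l1_ratios Elastic-net mixing values (default
#'   `c(0, 0.25, 0.5, 0.75, 1)`).
#' @return An `lr_grid` list.
#' @export
lr_grid <- function(feature_percentages = c(5, 10, 20),
                    inv_regularization = 10^(-4:4),
                    l1_ratios = c(0, 0.25, 0.5, 0.75, 1)) {
  if (length(feature_percentages) == 0L || length(inv_regularization) == 0L ||
      length(l1_ratios) == 0L) stop_mp("grid axes must be non-empty")
  if (any(feature_percentages <= 0 | feature_percentages > 100)) {
    stop_mp("feature percentages must be in (0, 100]")
  }
  structure(list(feature_percentages = sort(feature_percentages),
                 inv_regularization = sort(inv_regularization),
                 l1_ratios = sort(l1_ratios)),
            class = "lr_grid")
}

#' Random-forest tuning grid
#'
#' The default axes give 3 x 2 x 4 x 2 = 48 parameter combinations. Trees
#' per forest is fixed (`n_trees`), not searched. Note: tree induction
#' always uses the Gini impurity; the `criterion` axis is part of the
#' declared search space but both values map onto Gini splitting and
#' differ only in the RNG stream of the fit (see the methods vignette).
#'
#' @param max_depths Maximum tree depths (default `2:4`).
#' @param bootstrap Bootstrap resampling of samples per tree
#'   (default `c(TRUE, FALSE)`).
#' @param max_features Features considered per split: `"auto"`, `"sqrt"`,
#'   `"log2"`, `"none"` (auto = sqrt, its conventional classification
#'   meaning; none = all features).
#' @param criterion Split-quality axis (default `c("gini", "entropy")`).
#' @param n_trees Trees per forest (default 500).
#' @return An `rf_grid` list.
#' @export
rf_grid <- function(max_depths = 2:4, bootstrap = c(TRUE, FALSE),
                    max_features = c("auto", "sqrt", "log2", "none"),
                    criterion = c("gini", "entropy"), n_trees = 500) {
  if (length(max_depths) == 0L || length(bootstrap) == 0L ||
      length(max_features) == 0L || length(criterion) == 0L) {
    stop_mp("grid axes must be non-empty")
  }
  structure(list(max_depths = max_depths, bootstrap = bootstrap,
                 max_features = max_features, criterion = criterion,
                 n_trees = as.integer(n_trees)),
            class = "rf_grid")
}

#' Enumerate a tuning grid
#'
#' For the logistic grid, rows are ordered by the inner-loop tie-break
#' preference: smaller feature percentage, then smaller C, then larger
#' l1 ratio — the first row with maximal inner AUC wins.
#'
#' @param grid An `lr_grid` or `rf_grid`.
#' @return Data frame with one row per parameter combination.
#' @export
enumerate_grid <- function(grid) {
  if (inherits(grid, "lr_grid")) {
    df <- expand.grid(l1_ratio = grid$l1_ratios,
                      inv_reg = grid$inv_regularization,
                      pct = grid$feature_percentages,
                      KEEP.OUT.ATTRS = FALSE)
    df <- df[order(df$pct, df$inv_reg, -df$l1_ratio), c("pct", "inv_reg", "l1_ratio")]
    rownames(df) <- NULL
    return(df)
  }
  if (inherits(grid, "rf_grid")) {
    df <- expand.grid(criterion = grid$criterion,
                      max_features = grid$max_features,
                      bootstrap = grid$bootstrap,
                      max_depth = grid$max_depths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df <- df[, c("max_depth", "bootstrap", "max_features", "criterion")]
    rownames(df) <- NULL
    return(df)
  }
  stop_mp("unknown grid type")
}

#' Univariate feature ranking by training-fold t-test
#'
#' Features are ranked by ascending equal-variance t-test p-value computed
#' on the training samples only, and the top
#' `max(1, round(percentage / 100 * n_features))` are kept.
#'
#' @param X Numeric matrix, samples x features (training fold only).
#' @param y Binary labels aligned to rows of `X`.
#' @param percentage Percent of features to keep, in `(0, 100]`.
#' @return Character vector of selected feature names, best first.
#' @export
rank_features <- function(X, y, percentage) {
  if (percentage <= 0 || percentage > 100) stop_mp("percentage must be in (0, 100]")
  if (is.factor(y)) y <- as.integer(y) - 1L
  ts <- row_t_stats(t(X[y == 1L, , drop = FALSE]), t(X[y == 0L, , drop = FALSE]))
  ord <- order(ts$p, seq_along(ts$p))
  n_sel <- max(1L, round(percentage / 100 * ncol(X)))
  colnames(X)[ord[seq_len(n_sel)]]
}
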