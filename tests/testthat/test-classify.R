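test_that("auc matches brute-force pair counting, handles ties and complements", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(auc(scores, labels) + auc(scores, 1 - labels), 1)
  }
})

test_that("stratified folds cover each sample once and spread classes evenly", {
  y <- rep(c("A", "B"), c(19, 69))
  f <- stratified_folds(y, 5, seed = 4)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 88L)
  per_fold_a <- table(f[y == "A"])
  expect_lte(diff(range(per_fold_a)), 1)
  expect_identical(f, stratified_folds(y, 5, seed = 4))
})

test_that("grid enumeration yields the full parameter spaces", {
  expect_equal(nrow(enumerate_grid(lr_grid())), 135L)
  expect_equal(nrow(enumerate_grid(rf_grid())), 48L)
})

test_that("feature ranking keeps the rounded percentage with a floor of one", {
  set.seed(8)
  X <- matrix(rnorm(20 * 246), nrow = 20, dimnames = list(NULL, paste0("m", 1:246)))
  y <- rep(0:1, each = 10)
  expect_length(rank_features(X, y, 20), 49L)   # round(49.2)
  expect_length(rank_features(X, y, 5), 12L)    # round(12.3)
  expect_length(rank_features(X, y, 10), 25L)   # round(24.6)
  expect_length(rank_features(X, y, 0.01), 1L)  # floor of one

  # a perfectly separating feature is always ranked first
  X[, "m7"] <- y + rnorm(20, sd = 0.01)
  expect_equal(rank_features(X, y, 5)[1], "m7")
  expect_error(rank_features(X, y, 0), "\\(0, 100\\]")
})

test_that("elastic-net logistic obeys its penalty limits", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), nrow = 40, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(plogis(2 * X[, 1] - X[, 2]) > runif(40))
  if (length(unique(y)) < 2) y[1:2] <- 0:1

  # ridge with huge C approaches the unpenalized fit
  loose <- fit_elastic_logistic(X, y, inv_reg = 1e8, l1_ratio = 0)
  ref <- glm(y ~ scale(X), family = binomial)
  expect_equal(unname(loose$beta), unname(coef(ref)[-1]), tolerance = 1e-2)

  # lasso with tiny C shrinks everything to zero
  tight <- fit_elastic_logistic(X, y, inv_reg = 1e-6, l1_ratio = 1)
  expect_true(all(tight$beta == 0))
  expect_equal(diff(range(predict(tight, X))), 0)

  # separable single-feature toy reaches AUC 1 at moderate penalty
  Xt <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  yt <- c(0, 0, 1, 1)
  fit <- fit_elastic_logistic(Xt, yt, inv_reg = 1, l1_ratio = 0.5)
  expect_equal(auc(predict(fit, Xt), yt), 1.0)
})

test_that("nested CV separates planted classes and is deterministic", {
  sim <- simulate_cohort(small_cohort(seed = 21))
  nm <- normalize_chain(sim$ct)$normalized
  spec <- cv_spec(outer_folds = 3, inner_folds = 3, seed = 5)
  grid <- lr_grid(feature_percentages = c(10, 20),
                  inv_regularization = c(0.01, 1, 100),
                  l1_ratios = c(0, 0.5, 1))
  res <- nested_cv_logistic(nm, sim$annotation, positive = c("nTFHL", "nPTCL"),
                            grid = grid, spec = spec)
  expect_gte(res$mean_auc, 0.9)
  expect_length(res$fold_auc, 3L)
  expect_true(all(res$fold_auc >= 0 & res$fold_auc <= 1))
  # pooled predictions cover every sample exactly once
  expect_equal(sort(res$predictions$sample_id), sort(sim$annotation$sample_id))
  expect_false(anyNA(res$predictions$score))

  res2 <- nested_cv_logistic(nm, sim$annotation, positive = c("nTFHL", "nPTCL"),
                             grid = grid, spec = spec)
  expect_identical(res$fold_auc, res2$fold_auc)
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$fold_params, res2$fold_params)
})

test_that("permuted labels drive nested-CV AUC to chance (no leakage)", {
  sim <- simulate_cohort(small_cohort(seed = 22))
  nm <- normalize_chain(sim$ct)$normalized
  grid <- lr_grid(feature_percentages = 20, inv_regularization = c(0.1, 10),
                  l1_ratios = c(0, 1))
  aucs <- sapply(1:8, function(s) {
    ann <- sim$annotation
    set.seed(s + 100)
    ann$class <- sample(ann$class)
    nested_cv_logistic(nm, ann, positive = c("nTFHL", "nPTCL"),
                       grid = grid,
                       spec = cv_spec(outer_folds = 3, inner_folds = 3, seed = s))$mean_auc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("a validation-only spy feature cannot enter the selected panel", {
  sim <- simulate_cohort(small_cohort(seed = 23, effects = default_effects(n = 4)))
  nm <- normalize_chain(sim$ct)$normalized
  ann <- sim$annotation
  y_all <- as.integer(ann$class != "RLN")
  spec <- cv_spec(outer_folds = 3, inner_folds = 3, seed = 9)
  outer <- stratified_folds(y_all, 3, derive_seed(9L, "outer"))
  # the spy equals the label on fold-1 validation samples, noise elsewhere
  spy <- rnorm(length(y_all), sd = 0.01)
  spy[outer == 1] <- y_all[outer == 1] * 10
  nm$values <- rbind(nm$values, SPY = spy)
  res <- nested_cv_logistic(nm, ann, positive = c("nTFHL", "nPTCL"),
                            grid = lr_grid(feature_percentages = 10,
                                           inv_regularization = 1,
                                           l1_ratios = 0.5),
                            spec = spec)
  expect_false("SPY" %in% res$fold_features[[1]])
})

test_that("random-forest nested CV pools one prediction per sample into the confusion", {
  sim <- simulate_cohort(small_cohort(seed = 24))
  nm <- normalize_chain(sim$ct)$normalized
  grid <- rf_grid(max_depths = 3, bootstrap = TRUE, max_features = "sqrt",
                  criterion = "gini", n_trees = 100)
  rf <- nested_cv_random_forest(nm, sim$annotation, grid = grid,
                                spec = cv_spec(outer_folds = 3, inner_folds = 2, seed = 2))
  cm <- rf$confusion
  expect_equal(sum(cm$counts), nrow(sim$annotation))
  expect_equal(unname(rowSums(cm$fractions)), rep(1, 3))
  expect_equal(sort(rf$model$predictions$sample_id), sort(sim$annotation$sample_id))
  # shared lymphoma effects make the subtypes mutually confusable
  lymph <- cm$fractions["nPTCL", "nTFHL"] + cm$fractions["nTFHL", "nPTCL"]
  expect_gt(lymph, 0.3)
})

test_that("permutation importance is exactly zero for ignored features and finds drivers", {
  # hand-built scorer that only reads feature "good"
  scorer <- function(X) X[, "good"]
  set.seed(31)
  X <- matrix(rnorm(60 * 3), nrow = 60, dimnames = list(NULL, c("good", "junk1", "junk2")))
  y <- as.integer(X[, "good"] > 0)
  imp <- permutation_importance(scorer, X, y, metric = "auc", repeats = 10, seed = 3)
  expect_equal(imp$importance[imp$feature == "junk1"], 0)
  expect_equal(imp$importance[imp$feature == "junk2"], 0)
  expect_equal(imp$feature[1], "good")
  # a perfect single predictor loses (baseline - chance) when shuffled
  good_imp <- imp$importance[imp$feature == "good"]
  expect_equal(good_imp, 0.5, tolerance = 0.1)
  expect_error(permutation_importance(scorer, X, y, repeats = 1), ">= 2")

  imp2 <- permutation_importance(scorer, X, y, metric = "auc", repeats = 10, seed = 3)
  expect_identical(imp, imp2)
})

test_that("common_panel intersects per-model stable features", {
  mk <- function(feats) {
    structure(list(fold_features = feats), class = "model_result")
  }
  a <- mk(list(c("x", "y"), c("x", "y"), c("x", "y", "q")))
  b <- mk(list(c("y", "z"), c("y", "z"), c("y")))
  expect_equal(common_panel(list(a, b), min_fold_frequency = 0.8), "y")
  expect_length(common_panel(list(mk(list("a", "a")), mk(list("b", "b")))), 0L)
  expect_equal(common_panel(list(a), min_fold_frequency = 0.8), c("x", "y"))
})

test_that("mean outer AUC responds monotonically to planted shift magnitude", {
  grid <- lr_grid(feature_percentages = 20, inv_regularization = c(0.1, 10),
                  l1_ratios = c(0, 1))
  mean_auc_at <- function(shift) {
    aucs <- sapply(1:3, function(s) {
      eff <- if (shift == 0) default_effects(n = 8)[0, ] else
        data.frame(mirna = 1:8, class = "both-lymphomas",
                   shift = shift * rep_len(c(-1, 1), 8))
      sim <- simulate_cohort(small_cohort(seed = 40 + s, effects = eff))
      nm <- normalize_chain(sim$ct)$normalized
      nested_cv_logistic(nm, sim$annotation, positive = c("nTFHL", "nPTCL"),
                         grid = grid,
                         spec = cv_spec(outer_folds = 3, inner_folds = 3,
                                        seed = s))$mean_auc
    })
    mean(aucs)
  }
  curve <- sapply(c(0, 0.5, 1.0, 2.0), mean_auc_at)
  expect_true(all(diff(curve) >= -0.08))   # sampling-error tolerance
  expect_lt(curve[1], 0.75)
  expect_gt(curve[4], 0.9)
})
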