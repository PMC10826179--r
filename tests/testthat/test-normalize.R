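test_that("spikein_normalize removes per-sample offsets relative to the cohort median", {
  m <- tiny_ct_matrix()
  # spike means: 19, 20, 19, 21 -> median 19.5 -> offsets -0.5, 0.5, -0.5, 1.5
  norm <- spikein_normalize(m)
  expect_equal(unname(norm$ct["miR-a", ]), c(20.5, 20.5, 22.5, 21.5))
  expect_identical(norm$provenance, c("raw", "spikein"))
  # undetected wells keep their (missing) values
  expect_true(all(is.na(norm$ct["miR-d", ])))

  # identical spike-ins across samples -> unchanged
  ct <- rbind("miR-a" = c(20, 25), "SPIKE_1" = c(19, 19))
  colnames(ct) <- c("S1", "S2")
  m2 <- ct_matrix(ct, is_spike_in = c(FALSE, TRUE))
  expect_equal(spikein_normalize(m2)$ct["miR-a", ], m2$ct["miR-a", ])
})

test_that("spikein_normalize cancels planted offsets exactly when noise is disabled", {
  cfg <- cohort_config(n_mirnas = 30, n_low_detection = 0,
                       effects = default_effects(n = 3),
                       within_class_sd = 0, technical_offset_sd = 0.5, seed = 9)
  sim <- simulate_cohort(cfg)
  norm <- spikein_normalize(sim$ct)
  # after normalization every sample's spike-in mean equals the cohort constant
  sp <- norm$ct[norm$is_spike_in, , drop = FALSE]
  expect_lt(diff(range(colMeans(sp))), 1e-9)
  # and a constant-baseline (noise-free) miRNA is flat across same-class samples
  rln <- sim$annotation$sample_id[sim$annotation$class == "RLN"]
  expect_lt(diff(range(norm$ct[25, rln])), 1e-9)
})

test_that("spikein_normalize is idempotent and fails loudly on bad spike-ins", {
  m <- spikein_normalize(tiny_ct_matrix())
  m2 <- spikein_normalize(m)
  expect_equal(m2$ct, m$ct)

  ct <- rbind("miR-a" = c(20, 25))
  colnames(ct) <- c("S1", "S2")
  expect_error(spikein_normalize(ct_matrix(ct)), "no spike-in")

  ct3 <- rbind("miR-a" = c(20, 25), "SPIKE_1" = c(19, NA))
  colnames(ct3) <- c("S1", "S2")
  expect_error(spikein_normalize(ct_matrix(ct3, is_spike_in = c(FALSE, TRUE))),
               "S2")
})

test_that("filter_low_detection applies the strict less-than rule and drops spike-ins", {
  ct <- matrix(25, nrow = 3, ncol = 10,
               dimnames = list(c("none", "one", "SPIKE_1"), paste0("S", 1:10)))
  ct["none", ] <- NA            # 0/10 detected -> removed
  ct["one", 2:10] <- NA         # exactly 1/10 = 10% -> retained
  m <- ct_matrix(ct, is_spike_in = c(FALSE, FALSE, TRUE))
  flt <- filter_low_detection(m, min_fraction = 0.10)
  expect_identical(rownames(flt$matrix$ct), "one")
  expect_identical(flt$removed_ids, "none")
  expect_error(filter_low_detection(m, min_fraction = 0), "\\(0, 1\\]")
})

test_that("default synthetic cohort loses exactly the designated low-detection miRNAs", {
  sim <- simulate_cohort(cohort_config(seed = 2))
  flt <- filter_low_detection(sim$ct)
  expect_setequal(flt$removed_ids, sim$truth$low_detection_ids)
  expect_equal(nrow(flt$matrix$ct), 246L)
})

test_that("global_mean_normalize yields zero-mean -dCt values and checks provenance", {
  ct <- matrix(c(20, 22, 24, 25, 25, 25), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  m <- ct_matrix(ct)
  expect_error(global_mean_normalize(m), "filter_low_detection")
  m$provenance <- c("raw", "low_detection_filter")
  nm <- global_mean_normalize(m)
  expect_equal(unname(nm$values[, "S1"]), c(2, 0, -2))
  expect_equal(unname(nm$values[, "S2"]), c(0, 0, 0))
  expect_true(all(abs(colMeans(nm$values)) < 1e-9))
})

test_that("global_mean_normalize imputes undetected wells at the detection limit", {
  ct <- matrix(c(20, NA, 30, 25), nrow = 2,
               dimnames = list(c("a", "b"), c("S1", "S2")))
  m <- ct_matrix(ct)
  m$provenance <- c("raw", "low_detection_filter")
  nm <- global_mean_normalize(m, impute_ct = 35)
  expect_equal(unname(nm$values[, "S1"]), c(7.5, -7.5))   # mean(20, 35) = 27.5
})

test_that("global normalization is invariant to per-sample additive offsets", {
  # fully detected matrix: limit-imputed wells are pinned at 35 by design and
  # cannot follow a sample shift, so the exact guarantee applies to detected data
  cfg <- cohort_config(n_per_class = c(RLN = 10, nTFHL = 12, nPTCL = 10),
                       n_mirnas = 40, n_low_detection = 0,
                       baseline_ct_range = c(20, 28), within_class_sd = 0.5,
                       effects = default_effects(n = 4), seed = 6)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$ct$detected))
  flt <- filter_low_detection(sim$ct)$matrix
  nm1 <- global_mean_normalize(flt)
  shifted <- flt
  shifted$ct <- sweep(flt$ct, 2L, seq_len(ncol(flt$ct)) * 0.1, "+")
  nm2 <- global_mean_normalize(shifted)
  expect_equal(nm2$values, nm1$values)
})

test_that("the normalization chain commutes with sample permutation", {
  sim <- simulate_cohort(small_cohort(seed = 7))
  perm <- rev(seq_len(ncol(sim$ct$ct)))
  m2 <- sim$ct
  m2$ct <- m2$ct[, perm]
  m2$detected <- m2$detected[, perm]
  nm1 <- normalize_chain(sim$ct)$normalized
  nm2 <- normalize_chain(m2)$normalized
  expect_equal(nm2$values, nm1$values[, perm])
})

test_that("hierarchical clustering uses complete linkage on euclidean distances", {
  # three points at mutual distances 1, 1, 2: first merge at 1, final at 2
  vals <- matrix(c(0, 1, -1), nrow = 1, dimnames = list("m", c("A", "B", "C")))
  nm <- normalized_matrix(vals)
  cl <- hierarchical_cluster(nm, "samples")
  expect_equal(cl$height, c(1, 2))
  expect_true(all(diff(cl$height) >= 0))

  # identical samples merge at height zero
  vals2 <- matrix(c(1, 1, 5), nrow = 1, dimnames = list("m", c("A", "B", "C")))
  cl2 <- hierarchical_cluster(normalized_matrix(vals2), "samples")
  expect_equal(cl2$height[1], 0)

  expect_error(hierarchical_cluster(
    normalized_matrix(matrix(1, 1, 1, dimnames = list("m", "A"))), "samples"),
    "at least 2")
})

test_that("pca_summary centers variables and reports descending variance fractions", {
  # samples exactly on a line in miRNA space -> PC1 carries everything
  vals <- rbind(m1 = c(-2, 0, 2, 4), m2 = c(-1, 0, 1, 2))
  colnames(vals) <- paste0("S", 1:4)
  ps <- pca_summary(normalized_matrix(vals), n_components = 2)
  expect_equal(ps$variance_fraction[1], 1.0)

  # isotropic noise in 2 variables: about half the variance each
  set.seed(42)
  iso <- matrix(rnorm(2 * 10000), nrow = 2,
                dimnames = list(c("a", "b"), paste0("S", 1:10000)))
  ps2 <- pca_summary(normalized_matrix(iso), n_components = 2)
  expect_equal(ps2$variance_fraction[1], 0.5, tolerance = 0.05)
  expect_true(all(diff(ps2$variance_fraction) <= 0))
  expect_lte(sum(ps2$variance_fraction), 1 + 1e-9)

  expect_warning(pca_summary(normalized_matrix(vals), n_components = 10),
                 "truncated")
})
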