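test_that("targets_of unions target sets and logs skipped miRNAs", {
  map <- target_map(list(m1 = c("A", "B"), m2 = c("B", "C")))
  expect_setequal(as.character(targets_of(c("m1", "m2"), map)), c("A", "B", "C"))
  expect_length(targets_of(character(0), map), 0L)
  only_missing <- targets_of("m9", map)
  expect_length(only_missing, 0L)
  expect_equal(attr(only_missing, "n_skipped"), 1L)
})

test_that("hypergeometric_test is exact, inclusive and upper-tailed", {
  uni <- paste0("g", 1:10)
  res <- hypergeometric_test(targets = uni[1:5], pathway = uni[c(1:4)],
                             universe = uni)
  expect_equal(res$k, 4L)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)   # C(4,4) C(6,1) / C(10,5)

  # k = 0 -> upper tail includes everything
  res0 <- hypergeometric_test(uni[6:10], uni[1:3], uni)
  expect_equal(res0$k, 0L)
  expect_equal(res0$p, 1)

  # agreement with the enumeration oracle on random margins
  set.seed(13)
  for (i in 1:50) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    u <- paste0("g", 1:N)
    tg <- sample(u, n); pw <- sample(u, K)
    k <- length(intersect(tg, pw))
    expect_equal(hypergeometric_test(tg, pw, u)$p,
                 oracle_hyper_upper(k, N, K, n), tolerance = 1e-10)
  }
  expect_error(hypergeometric_test("a", "b", character(0)), "empty")
})

test_that("ks_enrichment matches the brute-force ECDF gap", {
  scores <- setNames(c(1, 1, 0, 0), paste0("g", 1:4))
  expect_equal(ks_enrichment(scores, c("g1", "g2")), 1)
  expect_equal(ks_enrichment(setNames(rep(2, 6), paste0("g", 1:6)), c("g1", "g2")), 0)
  expect_true(is.na(ks_enrichment(scores, character(0))))

  set.seed(17)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    sc <- setNames(sample(0:4, n, replace = TRUE), paste0("g", seq_len(n)))
    member <- sample(names(sc), sample(2:(n - 2), 1))
    expect_equal(ks_enrichment(sc, member),
                 oracle_ks_d(sc[member], sc[setdiff(names(sc), member)]),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values hit the formula floor and reject tiny B", {
  map <- simulate_target_map(30, 300, seed = 2)
  uni <- sort(unique(unlist(map)))
  pathway <- map[[1]]
  cfg <- enrichment_config(n_permutations = 99, seed = 7)
  p <- permutation_null(observed_stat = length(pathway) + 1, mirna_set_size = 3,
                        panel = names(map), map = map, pathway = pathway,
                        universe = uni, cfg = cfg)
  expect_equal(p, 1 / 100)   # observed beats every permutation
  expect_error(enrichment_config(n_permutations = 50), "at least 99")
})

test_that("permutation p-values are invariant to gene relabeling", {
  map <- simulate_target_map(20, 150, seed = 5)
  uni <- sort(unique(unlist(map)))
  pathway <- unique(unlist(map[1:3]))[1:10]
  cfg <- enrichment_config(n_permutations = 199, seed = 3)
  p1 <- permutation_null(5, 4, names(map), map, pathway, uni, cfg)
  relabel <- setNames(sprintf("X%04d", seq_along(uni)), uni)
  map2 <- target_map(lapply(unclass(map), function(g) unname(relabel[g])))
  p2 <- permutation_null(5, 4, names(map2), map2, unname(relabel[pathway]),
                         unname(relabel[uni]), cfg)
  expect_equal(p1, p2)
})

test_that("null permutation p-values are valid and uniform on the achievable grid", {
  map <- simulate_target_map(40, 400, seed = 9)
  uni <- sort(unique(unlist(map)))
  gene_scores <- function(de) {
    sc <- rowSums(sapply(de, function(m) uni %in% map[[m]]))
    setNames(sc, uni)
  }
  # discrete overlap-count statistic: heavy ties make p conservative
  # (P(p <= a) <= a), never anti-conservative
  set.seed(99)
  pk <- replicate(150, {
    de <- sample(names(map), 5)
    pathway <- sample(uni, 25)
    k <- length(intersect(as.character(targets_of(de, map)), pathway))
    permutation_null(k, 5, names(map), map, pathway, uni,
                     enrichment_config(n_permutations = 99,
                                       seed = sample.int(1e6, 1)))
  })
  expect_lte(mean(pk <= 0.05), 0.05 + 0.03)
  expect_gte(mean(pk), 0.45)

  # near-tie-free KS-D statistic: p is uniform under the self-drawn null
  set.seed(77)
  pd <- replicate(200, {
    de <- sample(names(map), 5)
    pathway <- sample(uni, 25)
    d <- ks_enrichment(gene_scores(de), pathway)
    permutation_null(d, 5, names(map), map, pathway, uni,
                     enrichment_config(n_permutations = 199,
                                       seed = sample.int(1e6, 1)),
                     statistic = "ks-D")
  })
  expect_gt(suppressWarnings(ks.test(pd, "punif"))$p.value, 0.01)
  expect_equal(mean(pd <= 0.05), 0.05, tolerance = 0.05)
})

test_that("enrich_all ranks a strongly planted set first and degrades gracefully", {
  map <- simulate_target_map(60, 600, seed = 12)
  gs <- simulate_gene_sets(
    map, planted = list(list(name = "PLANTED", source_mirnas = names(map)[1:6],
                             strength = 1.0)),
    n_null_sets = 30, set_size = c(20, 20), seed = 12)
  res <- enrich_all(names(map)[1:6], gs, map,
                    enrichment_config(n_permutations = 199, seed = 4))
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$set[1], "PLANTED")
  expect_equal(res$perm_p[1], 1 / 200)
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$q >= res$perm_p - 1e-15))

  # empty DE set: zero overlaps, all q = 1
  res0 <- enrich_all(character(0), gs, map,
                     enrichment_config(n_permutations = 99, seed = 4))
  expect_true(all(res0$k == 0))
  expect_true(all(res0$q == 1))
})

test_that("analytic and permutation orderings agree on the hypergeometric statistic", {
  map <- simulate_target_map(50, 500, seed = 20)
  gs <- simulate_gene_sets(map, planted = list(
    list(name = "P1", source_mirnas = names(map)[1:4], strength = 0.8),
    list(name = "P2", source_mirnas = names(map)[5:8], strength = 0.4)),
    n_null_sets = 30, set_size = c(20, 20), seed = 20)
  res <- enrich_all(names(map)[1:8], gs, map,
                    enrichment_config(n_permutations = 499, seed = 8))
  rho <- cor(rank(res$perm_p), rank(res$hyper_p), method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("stronger planted enrichment never weakens the permutation p", {
  strengths <- c(0.2, 0.6, 1.0)
  mean_p <- sapply(strengths, function(st) {
    ps <- sapply(1:10, function(s) {
      map <- simulate_target_map(40, 400, seed = s)
      gs <- simulate_gene_sets(map, planted = list(
        list(name = "P", source_mirnas = names(map)[1:5], strength = st)),
        n_null_sets = 5, set_size = c(20, 20), seed = s)
      res <- enrich_all(names(map)[1:5], gs, map,
                        enrichment_config(n_permutations = 99, seed = s))
      res$perm_p[res$set == "P"]
    })
    mean(ps)
  })
  expect_true(all(diff(mean_p) <= 0.02))
})
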