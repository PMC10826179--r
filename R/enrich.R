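#' Enrichment analysis configuration
#'
#' @param n_permutations Number of miRNA resamples B for the permutation
#'   null (default 1000, minimum 99).
#' @param seed Integer seed for the permutation draws.
#' @param universe Gene-universe policy: `"all-target-map-genes"`
#'   (competitive null over all measurable targets, the default) or
#'   `"gmt-universe"` (the collection's own universe).
#' @param alpha FDR threshold used when flagging enriched sets.
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(n_permutations = 1000, seed = 1L,
                              universe = c("all-target-map-genes", "gmt-universe"),
                              alpha = 0.05) {
  if (n_permutations < 99) stop_mp("need at least 99 permutations")
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 universe = match.arg(universe),
                 alpha = alpha),
            class = "enrichment_config")
}

#' Union of target genes of a miRNA set
#'
#' miRNAs absent from the map are skipped; their count is attached as the
#' `n_skipped` attribute.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param map A `target_map`.
#' @return Character vector of target gene symbols (the union).
#' @export
targets_of <- function(mirnas, map) {
  stopifnot(inherits(map, "target_map"))
  hit <- mirnas %in% names(map)
  genes <- sort(unique(unlist(map[mirnas[hit]], use.names = FALSE)))
  structure(genes, n_skipped = sum(!hit))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail, inclusive: `p = P(X >= k)` for
#' `X ~ Hypergeom(N = |universe|, K = |pathway|, n = |targets|)` where `k`
#' is the observed overlap. Target and pathway sets are first intersected
#' with the universe.
#'
#' @param targets Character vector of query genes.
#' @param pathway Character vector of pathway genes.
#' @param universe Character vector, the gene universe.
#' @return List with `k` (overlap), `p`, and the margins `K`, `n`, `N`.
#' @export
hypergeometric_test <- function(targets, pathway, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_mp("empty gene universe")
  targets <- intersect(targets, universe)
  pathway <- intersect(pathway, universe)
  k <- length(intersect(targets, pathway))
  N <- length(universe); K <- length(pathway); n <- length(targets)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, p = p, K = K, n = n, N = N,
       overlap = sort(intersect(targets, pathway)))
}

#' Two-sample Kolmogorov-Smirnov enrichment statistic
#'
#' D is the maximum gap between the empirical CDFs of the gene scores of
#' pathway members and non-members (scores are typically the number of
#' query miRNAs targeting each gene, so ties are heavy; the max-gap
#' definition handles them exactly).
#'
#' @param gene_scores Named numeric vector covering the universe (names =
#'   gene symbols).
#' @param pathway Character vector of pathway genes.
#' @return D in `[0, 1]`, or `NA` if the pathway or its complement is
#'   empty after universe restriction.
#' @export
ks_enrichment <- function(gene_scores, pathway) {
  if (is.null(names(gene_scores))) stop_mp("`gene_scores` must be named by gene")
  member <- names(gene_scores) %in% pathway
  if (!any(member) || all(member)) return(NA_real_)
  ks_stat_d(gene_scores[member], gene_scores[!member])
}

# max absolute ECDF gap, exact under ties
ks_stat_d <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
}

#' Permutation p-value under the miRNA-resampling null
#'
#' Resamples `mirna_set_size` miRNAs uniformly without replacement from
#' the measured panel B times; each draw is mapped to its target-gene
#' union and the chosen statistic recomputed, preserving the target
#' multiplicity of real miRNAs (the point of permuting miRNAs rather than
#' genes). `p = (1 + #{perm >= observed}) / (B + 1)`.
#'
#' @param observed_stat Observed statistic value.
#' @param mirna_set_size Size of the miRNA set being tested.
#' @param panel Character vector of measured miRNA ids to resample from.
#' @param map A `target_map`.
#' @param pathway Character vector of pathway genes.
#' @param universe Character vector, the gene universe.
#' @param cfg An [enrichment_config()].
#' @param statistic `"hypergeom-k"` (overlap count) or `"ks-D"`.
#' @return Permutation p-value in `[1/(B+1), 1]`.
#' @export
permutation_null <- function(observed_stat, mirna_set_size, panel, map,
                             pathway, universe, cfg = enrichment_config(),
                             statistic = c("hypergeom-k", "ks-D")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(map, "target_map"))
  if (mirna_set_size > length(panel)) stop_mp("set size exceeds the panel")
  pathway <- intersect(pathway, universe)
  B <- cfg$n_permutations
  inc <- target_incidence(map, universe)
  perm <- with_seed(cfg$seed, {
    vapply(seq_len(B), function(b) {
      draw <- sample(panel, mirna_set_size)
      cols <- intersect(draw, colnames(inc))
      if (statistic == "hypergeom-k") {
        hits <- rowSums(inc[pathway, cols, drop = FALSE]) > 0
        sum(hits)
      } else {
        scores <- rowSums(inc[, cols, drop = FALSE])
        ks_enrichment(scores, pathway)
      }
    }, 0)
  })
  (1 + sum(perm >= observed_stat, na.rm = TRUE)) / (B + 1)
}

# genes x miRNAs logical incidence matrix over a universe
target_incidence <- function(map, universe) {
  inc <- matrix(FALSE, nrow = length(universe), ncol = length(map),
                dimnames = list(universe, names(map)))
  for (m in names(map)) {
    g <- intersect(map[[m]], universe)
    inc[g, m] <- TRUE
  }
  inc
}

#' Gene-set enrichment of a differentially expressed miRNA set
#'
#' For each gene set: the overlap between the DE miRNAs' target-gene
#' union and the set (`k`, the "Counts"), the analytic hypergeometric p
#' (diagnostic), the KS D of targeting scores (members vs non-members),
#' and the primary permutation p under the miRNA-resampling null — one
#' shared batch of B miRNA draws scores every set. Benjamini-Hochberg q
#' is computed over the permutation p-values within the collection.
#'
#' @param de_mirnas Character vector of differentially expressed miRNA
#'   ids (e.g. a unique set from [de_set_partition()]).
#' @param collection A `gene_set_collection`.
#' @param map A `target_map`.
#' @param cfg An [enrichment_config()].
#' @param panel Measured miRNA ids resampled by the null (default: all
#'   miRNAs in the map; pass the retained panel when available).
#' @return An `enrichment_result` data.frame sorted by q then
#'   permutation p: `set`, `k`, `K`, `n`, `N`, `hyper_p`, `ks_d`,
#'   `perm_p`, `q`, `overlap_genes` (semicolon-joined).
#' @export
enrich_all <- function(de_mirnas, collection, map, cfg = enrichment_config(),
                       panel = names(map)) {
  stopifnot(inherits(collection, "gene_set_collection"), inherits(map, "target_map"))
  universe <- if (cfg$universe == "gmt-universe") collection$universe
              else sort(unique(unlist(map, use.names = FALSE)))
  sets <- lapply(collection$sets, intersect, y = universe)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (length(sets) == 0L) stop_mp("no gene set overlaps the universe")

  de_in_panel <- intersect(de_mirnas, panel)
  m_size <- length(de_in_panel)
  inc <- target_incidence(map, universe)
  de_cols <- intersect(de_in_panel, colnames(inc))
  score <- rowSums(inc[, de_cols, drop = FALSE])
  targets <- rownames(inc)[score > 0]

  hyper <- lapply(sets, function(s) hypergeometric_test(targets, s, universe))
  k_obs <- vapply(hyper, `[[`, 0, "k")
  ks_d <- vapply(sets, function(s) ks_enrichment(score, s), 0)

  # shared permutation draws: B x sets matrix of overlap counts
  B <- cfg$n_permutations
  set_inc <- matrix(FALSE, nrow = length(universe), ncol = length(sets),
                    dimnames = list(universe, names(sets)))
  for (s in names(sets)) set_inc[sets[[s]], s] <- TRUE
  if (m_size > 0L) {
    perm_ge <- integer(length(sets))
    with_seed(cfg$seed, {
      for (b in seq_len(B)) {
        draw <- intersect(sample(panel, m_size), colnames(inc))
        hit <- rowSums(inc[, draw, drop = FALSE]) > 0
        perm_k <- colSums(set_inc & hit)
        perm_ge <- perm_ge + as.integer(perm_k >= k_obs)
      }
    })
    perm_p <- (1 + perm_ge) / (B + 1)
  } else {
    perm_p <- rep(1, length(sets))
  }
  q <- bh_adjust(perm_p)

  res <- data.frame(
    set = names(sets),
    k = k_obs,
    K = vapply(hyper, `[[`, 0, "K"),
    n = length(targets),
    N = length(universe),
    hyper_p = vapply(hyper, `[[`, 0, "p"),
    ks_d = ks_d,
    perm_p = perm_p,
    q = q,
    overlap_genes = vapply(hyper, function(h) paste(h$overlap, collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[order(res$q, res$perm_p, res$set), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            n_de_mirnas = m_size, n_permutations = B, alpha = cfg$alpha)
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat(sprintf("<enrichment_result> %d sets | %d DE miRNAs | B = %d | %d sets at q < %g\n",
              nrow(x), attr(x, "n_de_mirnas"), attr(x, "n_permutations"),
              sum(x$q < attr(x, "alpha")), attr(x, "alpha")))
  print.data.frame(utils::head(x[, c("set", "k", "K", "hyper_p", "ks_d", "perm_p", "q")], n),
                   digits = 4)
  invisible(x)
}

#' Write an enrichment result as CSV
#'
#' @param res An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_result <- function(res, path) {
  utils::write.csv(as.data.frame(res), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
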