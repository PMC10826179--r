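#' Per-miRNA log2 fold change between two groups
#'
#' On the -dCt scale one Ct cycle equals one log2 unit, so the difference
#' of group means of normalized values is directly the log2 fold change.
#'
#' @param nm A `normalized_matrix`.
#' @param ann A `sample_annotation` covering every sample in `nm`.
#' @param group Character vector of class labels forming the comparison
#'   group (e.g. `c("nTFHL", "nPTCL")`).
#' @param ref Character vector of class labels forming the reference
#'   (default `"RLN"`).
#' @return Named numeric vector of log2 fold changes, one per miRNA.
#' @export
log2_fold_change <- function(nm, ann, group, ref = "RLN") {
  cls <- aligned_classes(ann, colnames(nm$values))
  gi <- cls %in% group
  ri <- cls %in% ref
  if (!any(gi) || !any(ri)) stop_mp("both comparison groups must be non-empty")
  rowMeans(nm$values[, gi, drop = FALSE]) - rowMeans(nm$values[, ri, drop = FALSE])
}

#' Two-sample Student's t-test (equal variance)
#'
#' Classic pooled-variance t with `length(x) + length(y) - 2` degrees of
#' freedom, two-sided. If the pooled variance is zero: equal means give
#' `p = 1` by convention; unequal means give the `p = 0` limit with an
#' infinite t.
#'
#' @param x,y Numeric vectors with at least 2 observations each.
#' @param welch If `TRUE`, use the Welch unequal-variance test instead.
#' @return List with `t` and `p`.
#' @export
student_t_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop_mp("each group needs >= 2 observations")
  if (welch) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    return(list(t = unname(ht$statistic), p = ht$p.value))
  }
  res <- row_t_stats(matrix(x, nrow = 1), matrix(y, nrow = 1))
  list(t = res$t[1], p = res$p[1])
}

# vectorized pooled-variance t over matrix rows; X and Y are
# features x samples slices of the two groups
row_t_stats <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  ss1 <- rowSums((X - m1)^2)
  ss2 <- rowSums((Y - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  # zero pooled variance: p = 1 for equal means, 0 limit otherwise
  degenerate <- se == 0
  t[degenerate & m1 == m2] <- 0
  t[degenerate & m1 != m2] <- sign(m1 - m2)[degenerate & m1 != m2] * Inf
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, p = p, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} (n p_(j) / j)`, capped
#' at 1 and mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_mp("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential expression of one comparison against a reference
#'
#' Per-miRNA log2 fold change and equal-variance Student's t between the
#' comparison group and the reference, with Benjamini-Hochberg FDR over
#' the comparison's own p-value family. A miRNA is called differentially
#' expressed when `q < alpha` (no fold-change floor).
#'
#' @param nm A `normalized_matrix`.
#' @param ann A `sample_annotation`.
#' @param group Class label(s) of the comparison group.
#' @param ref Class label(s) of the reference (default `"RLN"`).
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @param comparison Label stored with the result (default derived from
#'   `group`).
#' @param welch Use Welch's unequal-variance t instead (default `FALSE`).
#' @return A `de_result` data.frame sorted by q then p, with columns
#'   `mirna_id`, `log2fc`, `t`, `p`, `q`, `direction`, `significant`, and
#'   attributes `comparison` and `alpha`.
#' @export
differential_expression <- function(nm, ann, group, ref = "RLN", alpha = 0.05,
                                    comparison = paste(group, collapse = "+"),
                                    welch = FALSE) {
  cls <- aligned_classes(ann, colnames(nm$values))
  gi <- cls %in% group
  ri <- cls %in% ref
  if (sum(gi) < 2L || sum(ri) < 2L) stop_mp("each group needs >= 2 samples")
  X <- nm$values[, gi, drop = FALSE]
  Y <- nm$values[, ri, drop = FALSE]
  if (welch) {
    tt <- lapply(seq_len(nrow(X)), function(i) student_t_test(X[i, ], Y[i, ], welch = TRUE))
    t_stat <- vapply(tt, `[[`, 0, "t")
    p <- vapply(tt, `[[`, 0, "p")
  } else {
    ts <- row_t_stats(X, Y)
    t_stat <- ts$t
    p <- ts$p
  }
  lfc <- rowMeans(X) - rowMeans(Y)
  q <- bh_adjust(p)
  res <- data.frame(
    mirna_id = rownames(nm$values),
    log2fc = lfc, t = t_stat, p = p, q = q,
    direction = ifelse(lfc > 0, "up", "down"),
    significant = q < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[order(res$q, res$p, res$mirna_id), ]
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            comparison = comparison, alpha = alpha)
}

#' @export
print.de_result <- function(x, n = 10, ...) {
  cat(sprintf("<de_result> comparison %s vs reference: %d miRNAs, %d significant (q < %g; %d up, %d down)\n",
              attr(x, "comparison"), nrow(x), sum(x$significant), attr(x, "alpha"),
              sum(x$significant & x$direction == "up"),
              sum(x$significant & x$direction == "down")))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Significant miRNA ids of a DE result
#'
#' @param res A `de_result`.
#' @return Character vector of significant miRNA ids.
#' @export
significant_mirnas <- function(res) {
  stopifnot(inherits(res, "de_result"))
  res$mirna_id[res$significant]
}

#' Unique / shared partition of significant miRNA sets
#'
#' For each comparison, the miRNAs significant only there; plus the
#' intersection across all comparisons. Pure set algebra on the
#' significance calls.
#'
#' @param results Named list of >= 2 `de_result` objects.
#' @return List with per-comparison `unique` sets and the `shared` set.
#' @export
de_set_partition <- function(results) {
  if (length(results) < 2L) stop_mp("need >= 2 DE results to partition")
  if (is.null(names(results))) {
    names(results) <- vapply(results, attr, "", "comparison")
  }
  sig <- lapply(results, significant_mirnas)
  uniq <- lapply(seq_along(sig), function(i) {
    setdiff(sig[[i]], unlist(sig[-i], use.names = FALSE))
  })
  names(uniq) <- names(results)
  list(unique = uniq, shared = Reduce(intersect, sig))
}

#' Write a DE result as CSV
#'
#' @param res A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(res, path) {
  utils::write.csv(as.data.frame(res), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
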