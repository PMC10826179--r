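#' Spike-in technical normalization
#'
#' Estimates each sample's technical offset as the mean Ct of its spike-in
#' control wells minus the cohort median of those per-sample means (median
#' for robustness to a single aberrant sample), then subtracts the offset
#' from every detected Ct of the sample. A second application therefore
#' yields zero offsets. Requires every spike-in well to be detected.
#'
#' @param m A [ct_matrix] with at least one spike-in row.
#' @return The adjusted [ct_matrix]; provenance gains `"spikein"`.
#' @export
spikein_normalize <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  sp <- which(m$is_spike_in)
  if (length(sp) == 0L) stop_mp("no spike-in rows: spike-in normalization impossible")
  sp_det <- m$detected[sp, , drop = FALSE]
  if (!all(sp_det)) {
    bad <- colnames(m$ct)[colSums(!sp_det) > 0L]
    stop_mp("spike-in undetected in sample(s): ", paste(bad, collapse = ", "))
  }
  means <- colMeans(m$ct[sp, , drop = FALSE])
  offset <- means - stats::median(means)
  adj <- m$ct - rep(offset, each = nrow(m$ct))
  adj[!m$detected] <- m$ct[!m$detected]   # only detected wells are adjusted
  adj <- pmin(pmax(adj, 0), 45)
  out <- ct_matrix(adj, is_spike_in = m$is_spike_in, max_ct = m$max_ct,
                   provenance = m$provenance)
  # adjustment must not flip detection flags: keep the original calls
  out$detected <- m$detected
  append_provenance(out, "spikein")
}

#' Remove low-detection miRNAs (and spike-in rows)
#'
#' A miRNA is kept iff its detected fraction is at least `min_fraction`
#' (strict "less than" removal, so exactly 10% detection survives the
#' default cutoff). Spike-in rows are always removed at this step: they are
#' controls, not analytes.
#'
#' @param m A [ct_matrix].
#' @param min_fraction Minimum detected fraction to retain (default 0.10).
#' @return A list: `matrix` (filtered [ct_matrix], provenance gains
#'   `"low_detection_filter"`) and `removed_ids` (low-detection miRNA ids,
#'   excluding spike-ins).
#' @export
filter_low_detection <- function(m, min_fraction = 0.10) {
  stopifnot(inherits(m, "ct_matrix"))
  assert_scalar_num(min_fraction, "min_fraction", 0, 1)
  if (min_fraction <= 0) stop_mp("`min_fraction` must be in (0, 1]")
  frac <- rowMeans(m$detected)
  low <- frac < min_fraction & !m$is_spike_in
  keep <- !low & !m$is_spike_in
  if (!any(keep)) stop_mp("no miRNAs survive the low-detection filter")
  out <- ct_matrix(m$ct[keep, , drop = FALSE],
                   is_spike_in = rep(FALSE, sum(keep)),
                   max_ct = m$max_ct, provenance = m$provenance)
  out$detected <- m$detected[keep, , drop = FALSE]
  list(matrix = append_provenance(out, "low_detection_filter"),
       removed_ids = rownames(m$ct)[low])
}

#' Global-mean normalization to -dCt expression values
#'
#' Residual undetected wells are imputed at the detection limit
#' (`impute_ct`, conservative for low-abundance species), then each
#' sample's mean Ct is subtracted from its wells and the sign flipped:
#' `value(i, j) = -(ct(i, j) - mean_i ct(i, j))`, so higher values mean
#' higher abundance and downstream group differences read directly as log2
#' fold changes. Each sample's values average exactly zero. The
#' low-detection filter must have been applied first (checked through the
#' provenance trail).
#'
#' @param m A filtered [ct_matrix].
#' @param impute_ct Ct imputed into undetected wells (default 35).
#' @return A `normalized_matrix`: list with `values` (miRNAs x samples,
#'   no missing entries) and `provenance`.
#' @export
global_mean_normalize <- function(m, impute_ct = 35) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!"low_detection_filter" %in% m$provenance) {
    stop_mp("apply filter_low_detection() before global-mean normalization")
  }
  ct <- m$ct
  ct[!m$detected] <- impute_ct
  values <- -sweep(ct, 2L, colMeans(ct))
  normalized_matrix(values, provenance = c(m$provenance, "global_mean"))
}

#' Construct a normalized expression matrix
#'
#' @param values Numeric matrix (miRNAs x samples, no `NA`s), oriented so
#'   higher = more abundant.
#' @param provenance Processing-step names.
#' @return A `normalized_matrix`.
#' @export
normalized_matrix <- function(values, provenance = character()) {
  if (!is.matrix(values) || anyNA(values)) {
    stop_mp("`values` must be a complete numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_mp("`values` must carry dimnames")
  }
  structure(list(values = values, provenance = as.character(provenance)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d miRNAs x %d samples (-dCt scale)\n",
              nrow(x$values), ncol(x$values)))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Write a normalized matrix as CSV
#'
#' @param nm A `normalized_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized_matrix <- function(nm, path) {
  stopifnot(inherits(nm, "normalized_matrix"))
  df <- data.frame(mirna_id = rownames(nm$values), nm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full preprocessing chain: spike-in -> filter -> global mean
#'
#' @param m A raw [ct_matrix].
#' @param min_fraction Detection-fraction cutoff (default 0.10).
#' @param impute_ct Imputation value for residual undetected wells.
#' @return List with `normalized` (a `normalized_matrix`) and
#'   `removed_ids`.
#' @export
normalize_chain <- function(m, min_fraction = 0.10, impute_ct = 35) {
  flt <- filter_low_detection(spikein_normalize(m), min_fraction)
  list(normalized = global_mean_normalize(flt$matrix, impute_ct),
       removed_ids = flt$removed_ids)
}

#' Agglomerative clustering of samples or miRNAs
#'
#' Euclidean distance with complete linkage, so merge heights are
#' non-decreasing along the merge sequence.
#'
#' @param nm A `normalized_matrix`.
#' @param axis `"samples"` (default) or `"mirnas"`.
#' @return A `cluster_result`: list with `merge`, `height`, `order`,
#'   `labels`, `dist_method`, `linkage`, plus the underlying `hclust`.
#' @export
hierarchical_cluster <- function(nm, axis = c("samples", "mirnas")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  axis <- match.arg(axis)
  x <- if (axis == "samples") t(nm$values) else nm$values
  if (nrow(x) < 2L) stop_mp("need at least 2 items on axis '", axis, "'")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, dist_method = "euclidean", linkage = "complete",
         hclust = hc),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d leaves, %s distance, %s linkage\n",
              length(x$labels), x$dist_method, x$linkage))
  invisible(x)
}

#' PCA summary of a normalized matrix
#'
#' Samples are observations and miRNAs variables; variables are centered
#' but not scaled (all share the Ct scale). Variance fractions come from
#' the squared singular values.
#'
#' @param nm A `normalized_matrix`.
#' @param n_components Number of components summarized (default 10,
#'   truncated with a warning if larger than the data admit).
#' @return A `pca_summary`: `variance_fraction` (descending) and `scores`
#'   (samples on the first two components).
#' @export
pca_summary <- function(nm, n_components = 10) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- t(nm$values)
  if (nrow(x) < 2L) stop_mp("need at least 2 samples for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k_max <- length(pc$sdev)
  if (n_components > k_max) {
    warning(sprintf("n_components truncated from %d to %d", n_components, k_max),
            call. = FALSE)
    n_components <- k_max
  }
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(variance_fraction = frac[seq_len(n_components)],
         scores = pc$x[, seq_len(min(2L, k_max)), drop = FALSE]),
    class = "pca_summary"
  )
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("<pca_summary> PC1 %.1f%%, PC1+2 %.1f%% of variance\n",
              100 * x$variance_fraction[1],
              100 * sum(x$variance_fraction[seq_len(min(2, length(x$variance_fraction)))])))
  invisible(x)
}
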