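#' Threshold-cycle (Ct) matrix with detection and spike-in flags
#'
#' Container for raw or adjusted qPCR Ct values of a focused miRNA panel:
#' a numeric matrix (miRNAs x samples, `NA` = no amplification call), a
#' parallel logical detection matrix, a per-miRNA spike-in flag, and an
#' append-only provenance trail of the processing steps applied. A well is
#' "detected" iff a numeric Ct no greater than `max_ct` is present; lower
#' Ct means higher abundance (1 Ct is about one log2 unit).
#'
#' @param ct Numeric matrix, miRNAs in rows, samples in columns, with
#'   rownames/colnames set; values in `[0, 45]` or `NA`.
#' @param is_spike_in Logical vector, one flag per row of `ct`.
#' @param max_ct Detection limit in cycles (default 35, the conventional
#'   qPCR cutoff); values above it are retained but flagged undetected.
#' @param provenance Character vector of processing-step names.
#' @return An object of class `ct_matrix` with fields `ct`, `detected`,
#'   `is_spike_in`, `max_ct`, `provenance`.
#' @export
ct_matrix <- function(ct, is_spike_in = rep(FALSE, nrow(ct)), max_ct = 35,
                      provenance = "raw") {
  if (!is.matrix(ct) || !is.numeric(ct)) stop_mp("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop_mp("`ct` must carry miRNA rownames and sample colnames")
  }
  if (anyDuplicated(rownames(ct))) stop_mp("duplicate miRNA ids")
  if (anyDuplicated(colnames(ct))) stop_mp("duplicate sample ids")
  if (any(ct < 0 | ct > 45, na.rm = TRUE)) stop_mp("Ct values must lie in [0, 45]")
  if (length(is_spike_in) != nrow(ct)) stop_mp("`is_spike_in` length must match rows")
  assert_scalar_num(max_ct, "max_ct", 0, 45)
  structure(
    list(
      ct = ct,
      detected = !is.na(ct) & ct <= max_ct,
      is_spike_in = as.logical(is_spike_in),
      max_ct = max_ct,
      provenance = as.character(provenance)
    ),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf(
    "<ct_matrix> %d miRNAs (%d spike-in) x %d samples\n",
    nrow(x$ct), sum(x$is_spike_in), ncol(x$ct)
  ))
  cat(sprintf(
    "  detected wells: %.1f%%  |  max_ct: %g\n",
    100 * mean(x$detected), x$max_ct
  ))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

mirna_ids <- function(m) rownames(m$ct)
sample_ids_of <- function(m) colnames(m$ct)

append_provenance <- function(m, step) {
  m$provenance <- c(m$provenance, step)
  m
}

#' Read a Ct matrix from CSV
#'
#' Expects a header row of sample ids with a leading miRNA-id column; blank
#' cells are undetected wells. Rows whose id starts with `spike_in_prefix`
#' are flagged as spike-in controls. Cells above `max_ct` keep their value
#' but are flagged undetected.
#'
#' @param path CSV file path.
#' @param max_ct Detection cutoff in cycles (default 35).
#' @param spike_in_prefix Id prefix marking spike-in control rows
#'   (default `"SPIKE_"`).
#' @return A [ct_matrix].
#' @export
read_ct_matrix <- function(path, max_ct = 35, spike_in_prefix = "SPIKE_") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop_mp("Ct CSV needs a miRNA-id column plus >=1 sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop_mp("duplicate miRNA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop_mp("duplicate sample ids: ",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_mp(sprintf(
      "non-numeric cell(s): %s",
      paste(sprintf("row %s / sample %s ('%s')", ids[bad[, 1L]],
                    samples[bad[, 2L]], cells[bad]), collapse = "; ")
    ))
  }
  dimnames(num) <- list(ids, samples)
  spikes <- startsWith(ids, spike_in_prefix)
  if (!any(spikes)) {
    warning("no spike-in rows found (prefix '", spike_in_prefix,
            "'); spike-in normalization will not be possible", call. = FALSE)
  }
  ct_matrix(num, is_spike_in = spikes, max_ct = max_ct)
}

#' Write a Ct matrix to CSV
#'
#' Inverse of [read_ct_matrix()]: undetected missing wells become blank
#' cells; spike-in flags are carried by the row-id prefix, so ids of
#' spike-in rows must already carry it.
#'
#' @param m A [ct_matrix].
#' @param path Output CSV path.
#' @param digits Decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(m, path, digits = 6) {
  stopifnot(inherits(m, "ct_matrix"))
  cells <- ifelse(is.na(m$ct), "", formatC(m$ct, format = "f", digits = digits))
  df <- data.frame(mirna_id = rownames(m$ct), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("mirna_id", colnames(m$ct))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample class annotations
#'
#' Two-column CSV `sample_id,class` mapping each profiled sample to one of
#' the three diagnostic classes: `RLN` (reactive lymph node), `nTFHL`
#' (nodal T-follicular-helper-cell lymphoma) or `nPTCL` (nodal peripheral
#' T-cell lymphoma, NOS). Unrecognized labels can be mapped through
#' `aliases` (e.g. `c("PTCL-NOS" = "nPTCL")`); anything else is rejected.
#'
#' @param path CSV file path.
#' @param aliases Named character vector mapping foreign labels to
#'   canonical ones.
#' @return A `sample_annotation`: data.frame with columns `sample_id` and
#'   `class` (factor with levels RLN, nTFHL, nPTCL).
#' @export
read_sample_annotations <- function(path, aliases = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% colnames(df))) {
    stop_mp("annotation CSV must have columns sample_id,class")
  }
  sample_annotation(df$sample_id, df$class, aliases = aliases)
}

#' Construct a sample annotation
#'
#' @param sample_id Character vector of sample ids (unique).
#' @param class Character vector of class labels.
#' @param aliases Optional named character vector of label aliases.
#' @return A `sample_annotation` data.frame.
#' @export
sample_annotation <- function(sample_id, class, aliases = NULL) {
  levels <- c("RLN", "nTFHL", "nPTCL")
  class <- as.character(class)
  if (!is.null(aliases)) {
    hit <- class %in% names(aliases)
    class[hit] <- unname(aliases[class[hit]])
  }
  bad <- which(!class %in% levels)
  if (length(bad) > 0L) {
    stop_mp(sprintf("unknown class label(s): %s",
                    paste(sprintf("'%s' (sample %s)", class[bad], sample_id[bad]),
                          collapse = ", ")))
  }
  if (anyDuplicated(sample_id)) {
    stop_mp("duplicate sample id(s): ",
            paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  structure(
    data.frame(sample_id = as.character(sample_id),
               class = factor(class, levels = levels),
               stringsAsFactors = FALSE),
    class = c("sample_annotation", "data.frame")
  )
}

# class labels aligned to the columns of a ct_matrix / normalized_matrix
aligned_classes <- function(ann, sample_ids) {
  stopifnot(inherits(ann, "sample_annotation"))
  missing <- setdiff(sample_ids, ann$sample_id)
  if (length(missing) > 0L) {
    stop_mp("samples without annotation: ", paste(missing, collapse = ", "))
  }
  ann$class[match(sample_ids, ann$sample_id)]
}
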