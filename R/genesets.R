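#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes repeated within a
#' line are stored once; gene symbols are upper-cased.
#'
#' @param path GMT file path.
#' @param universe Optional character vector overriding the gene universe;
#'   by default the union of all sets.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors), `descriptions` (named character) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_mp("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_mp("GMT line(s) with fewer than 3 fields: line ",
            paste(short, collapse = ", "))
  }
  names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names)) stop_mp("duplicate gene-set names in GMT")
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- names
  names(desc) <- names
  gene_set_collection(sets, descriptions = desc, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors (non-empty).
#' @param descriptions Optional named character vector of set descriptions.
#' @param universe Optional gene universe; defaults to the union of all
#'   sets. Sets are restricted to the universe when one is supplied.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) == 0L || is.null(names(sets))) stop_mp("`sets` must be a named list")
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) stop_mp("empty gene set(s): ",
                                        paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(toupper(as.character(universe)))
    sets <- lapply(sets, intersect, y = universe)
    keep <- lengths(sets) > 0L
    sets <- sets[keep]
    if (length(sets) == 0L) stop_mp("no gene set overlaps the supplied universe")
  }
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(
    list(sets = sets, descriptions = descriptions[names(sets)], universe = universe),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  cat(sprintf("  set sizes: %d-%d (median %g)\n",
              min(lengths(x$sets)), max(lengths(x$sets)),
              stats::median(lengths(x$sets))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-to-target-gene map
#'
#' Tab-separated table in the layout of curated miRNA-target interaction
#' databases: a header containing at least columns `miRNA`, `Target Gene`
#' and `Support Type` (extra columns ignored). Rows whose support type is
#' not in `allowed_evidence` are dropped, keeping only strongly supported
#' interactions by default; remaining rows are aggregated per miRNA.
#'
#' @param path TSV file path.
#' @param allowed_evidence Character vector of accepted support types
#'   (default `"Functional MTI"`).
#' @return A `target_map`: named list, miRNA id -> character vector of
#'   upper-cased target gene symbols.
#' @export
read_target_map <- function(path, allowed_evidence = "Functional MTI") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("miRNA", "Target Gene", "Support Type")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop_mp("target map is missing column(s): ", paste(missing, collapse = ", "))
  }
  keep <- df[["Support Type"]] %in% allowed_evidence
  df <- df[keep, , drop = FALSE]
  target_map(split(toupper(df[["Target Gene"]]), df[["miRNA"]]))
}

#' Construct a miRNA target map
#'
#' @param map Named list: miRNA id -> character vector of target genes
#'   (each non-empty; deduplicated and upper-cased here).
#' @return A `target_map`.
#' @export
target_map <- function(map) {
  if (length(map) > 0L && is.null(names(map))) stop_mp("`map` must be named by miRNA id")
  map <- lapply(map, function(g) unique(toupper(as.character(g))))
  map <- map[lengths(map) > 0L]
  structure(map, class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> %d miRNAs -> %d distinct target genes\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}

#' Write a target map as TSV
#'
#' @param map A `target_map`.
#' @param path Output path.
#' @param support_type Support-type tag written for every pair.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(map, path, support_type = "Functional MTI") {
  stopifnot(inherits(map, "target_map"))
  df <- data.frame(
    miRNA = rep(names(map), lengths(map)),
    `Target Gene` = unlist(map, use.names = FALSE),
    `Support Type` = support_type,
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
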