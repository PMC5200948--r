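#' Per-gene feature-by-sample count container
#'
#' Holds one gene's q x n matrix of non-negative integer counts, with
#' feature identifiers as row names and sample identifiers as column names.
#' Per-sample totals (the multinomial denominators) are available via
#' [column_totals()]; they are treated as ancillary throughout, so no
#' library-size normalization is ever applied.
#'
#' @param gene_id Gene identifier (single string).
#' @param counts Numeric matrix of non-negative integers, features in rows,
#'   samples in columns. Must carry unique row and column names unless
#'   `feature_ids` / `sample_ids` are given.
#' @param feature_ids,sample_ids Optional identifier vectors overriding the
#'   matrix dimnames.
#' @return An object of class `gene_counts`.
#' @export
gene_counts <- function(gene_id, counts, feature_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  if (!is.character(gene_id) || length(gene_id) != 1L || is.na(gene_id))
    stop("'gene_id' must be a single string")
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  if (is.null(feature_ids))
    feature_ids <- sprintf("f%d", seq_len(nrow(counts)))
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%d", seq_len(ncol(counts)))
  if (anyDuplicated(feature_ids))
    stop("feature ids must be unique within a gene")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(as.character(feature_ids), as.character(sample_ids))
  structure(list(gene_id = gene_id, counts = counts), class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("gene_counts: ", x$gene_id, " (", nrow(x$counts), " features x ",
      ncol(x$counts), " samples)\n", sep = "")
  print(utils::head(x$counts, 6))
  invisible(x)
}

#' Per-sample total counts of a gene
#'
#' @param x A `gene_counts` object.
#' @return Named numeric vector of column sums.
#' @export
column_totals <- function(x) {
  stopifnot(inherits(x, "gene_counts"))
  colSums(x$counts)
}

#' Multi-gene dataset
#'
#' A list of [gene_counts()] objects sharing the same samples.
#'
#' @param genes List of `gene_counts` objects with identical sample ids.
#' @return An object of class `dm_data` (a named list of `gene_counts`).
#' @export
dm_data <- function(genes) {
  if (!is.list(genes) || (length(genes) > 0 &&
      !all(vapply(genes, inherits, logical(1), "gene_counts"))))
    stop("'genes' must be a list of gene_counts objects")
  if (length(genes) > 0) {
    ids <- vapply(genes, `[[`, character(1), "gene_id")
    if (anyDuplicated(ids)) stop("duplicate gene ids")
    samp <- colnames(genes[[1]]$counts)
    ok <- vapply(genes, function(g) identical(colnames(g$counts), samp),
                 logical(1))
    if (!all(ok)) stop("all genes must share the same sample ids, in order")
    names(genes) <- ids
  }
  structure(genes, class = "dm_data")
}

#' @export
print.dm_data <- function(x, ...) {
  n <- if (length(x) > 0) ncol(x[[1]]$counts) else 0
  q <- if (length(x) > 0) range(vapply(x, function(g) nrow(g$counts), 1)) else c(0, 0)
  cat("dm_data: ", length(x), " genes, ", n, " samples, ",
      q[1], "-", q[2], " features per gene\n", sep = "")
  invisible(x)
}

#' @export
`[.dm_data` <- function(x, i) {
  dm_data(unclass(x)[i])
}

#' Sample identifiers of a dataset
#' @param x A `dm_data` object.
#' @return Character vector of sample ids (empty dataset gives `character(0)`).
#' @export
dm_samples <- function(x) {
  stopifnot(inherits(x, "dm_data"))
  if (length(x) == 0) character(0) else colnames(x[[1]]$counts)
}

# Reorder the samples (columns) of every gene; used to canonicalize sample
# order so results do not depend on input order.
.reorder_samples <- function(x, ids) {
  dm_data(lapply(unclass(x), function(g) {
    gene_counts(g$gene_id, g$counts[, ids, drop = FALSE])
  }))
}

# Coerce a grouping specification (factor or vector, optionally named by
# sample id) to a factor aligned with the dataset's samples.
.align_group <- function(group, sample_ids) {
  if (!is.null(names(group))) {
    missing <- setdiff(sample_ids, names(group))
    if (length(missing) > 0)
      stop("no group assignment for sample(s): ",
           paste(missing, collapse = ", "))
    group <- group[sample_ids]
  } else if (length(group) != length(sample_ids)) {
    stop("'group' must be named by sample id or have one entry per sample")
  }
  factor(unname(group))
}
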