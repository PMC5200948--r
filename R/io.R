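# Tabular dialect: tab-delimited, header row, UTF-8, "." or "NA" as missing.

#' Read a feature count table
#'
#' Wide TSV with columns `gene_id`, `feature_id`, then one integer column
#' per sample. Rows are grouped by gene preserving input feature order.
#' Malformed input (ragged rows, duplicate gene/feature pairs, negative or
#' non-integer counts) is rejected with the offending line number.
#'
#' @param path Path to the TSV file.
#' @return A [dm_data()] dataset.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop("empty counts file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3 || header[1] != "gene_id" || header[2] != "feature_id")
    stop("counts header must start with gene_id, feature_id: ", path)
  samples <- header[-(1:2)]
  if (anyDuplicated(samples)) stop("duplicate sample columns in ", path)
  n <- length(header)
  body <- fields[-1]
  for (i in seq_along(body)) {
    if (length(body[[i]]) != n)
      stop("line ", i + 1, ": expected ", n, " fields, found ",
           length(body[[i]]))
  }
  gene_id <- vapply(body, `[[`, character(1), 1)
  feature_id <- vapply(body, `[[`, character(1), 2)
  if (anyDuplicated(paste(gene_id, feature_id, sep = "\r")))
    stop("duplicate (gene_id, feature_id) pair in ", path)
  vals <- matrix(NA_real_, length(body), length(samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-(1:2)]))
    if (any(is.na(v)))
      stop("line ", i + 1, ": non-numeric count")
    if (any(v < 0))
      stop("line ", i + 1, ": negative count")
    if (any(v != round(v)))
      stop("line ", i + 1, ": non-integer count")
    vals[i, ] <- v
  }
  colnames(vals) <- samples
  idx <- split(seq_along(body), factor(gene_id, levels = unique(gene_id)))
  genes <- lapply(names(idx), function(g) {
    rows <- idx[[g]]
    m <- vals[rows, , drop = FALSE]
    rownames(m) <- feature_id[rows]
    gene_counts(g, m)
  })
  dm_data(genes)
}

#' Write a feature count table
#'
#' @param data A [dm_data()] dataset.
#' @param path Output TSV path (written atomically).
#' @export
write_counts <- function(data, path) {
  stopifnot(inherits(data, "dm_data"))
  samples <- dm_samples(data)
  rows <- lapply(unclass(data), function(g) {
    data.frame(gene_id = g$gene_id, feature_id = rownames(g$counts),
               g$counts, check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  .write_tsv_atomic(tab, path)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id` and `group`.
#'
#' @param path Path to the TSV file.
#' @return Factor of group labels named by sample id.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("design file must have columns sample_id, group: ", path)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in ", path)
  stats::setNames(factor(tab$group), tab$sample_id)
}

#' Read SNP genotypes from VCF or TSV
#'
#' VCF genotypes are taken from the GT field as the dosage of the alternate
#' allele; half calls and `./.` become missing, and multi-allelic rows are
#' skipped with a counted warning (only bi-allelic SNPs are analyzed). The
#' TSV dialect has columns `snp_id`, `chrom`, `pos`, then one dosage column
#' per sample with values 0/1/2 and `.` or `NA` for missing.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [snp_set()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multi-allelic VCF row(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dosage <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (length(alleles) != 2 || any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  snp_set(data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     stringsAsFactors = FALSE),
          dosage)
}

.read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", "."))
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("genotype TSV must have columns snp_id, chrom, pos: ", path)
  dosage <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  storage.mode(dosage) <- "double"
  snp_set(tab[, need], dosage)
}

#' Read gene regions from GFF3 or BED
#'
#' Import goes through `rtracklayer`, so BED's 0-based half-open intervals
#' arrive converted to the 1-based inclusive convention used throughout.
#' For GFF3, rows with `type == "gene"` are used when present, and the gene
#' identifier is taken from the `ID`, `gene_id` or `Name` attribute; for
#' BED, from the name column.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param window Cis-window flank in bp (see [gene_regions()]).
#' @return A [gene_regions()] table.
#' @export
read_regions <- function(path, format = c("auto", "gff3", "bed"),
                         window = 5000) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df) && any(df$type == "gene"))
      df <- df[df$type == "gene", , drop = FALSE]
    id <- df$ID
    if (is.null(id)) id <- df$gene_id
    if (is.null(id)) id <- df$Name
    if (is.null(id) || any(is.na(id) | id == ""))
      stop("missing gene identifier in ", path)
  } else {
    id <- df$name
    if (is.null(id) || any(is.na(id) | id == ""))
      stop("missing name column in BED file ", path)
  }
  gene_regions(data.frame(gene_id = as.character(id),
                          chrom = as.character(df$seqnames),
                          start = df$start, end = df$end,
                          stringsAsFactors = FALSE),
               window = window)
}

#' Write a results table as TSV
#'
#' @param results Data frame (e.g. `dm_test` or `dm_tuqtl`).
#' @param path Output path (written atomically).
#' @export
write_results <- function(results, path) {
  .write_tsv_atomic(as.data.frame(results), path)
  invisible(path)
}

.write_tsv_atomic <- function(tab, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
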