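#' SNP genotype container
#'
#' Minor-allele dosage genotypes for a set of bi-allelic SNPs.
#'
#' @param info Data frame with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param dosage Numeric matrix, SNPs in rows (named as `info$snp_id`),
#'   samples in columns; entries 0, 1, 2 or `NA`.
#' @return Object of class `snp_set`.
#' @export
snp_set <- function(info, dosage) {
  stopifnot(is.data.frame(info),
            all(c("snp_id", "chrom", "pos") %in% names(info)))
  dosage <- as.matrix(dosage)
  if (nrow(info) != nrow(dosage)) stop("info and dosage disagree on SNPs")
  if (any(info$pos < 1)) stop("positions must be >= 1")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0 && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(info$snp_id)) stop("duplicate snp ids")
  rownames(dosage) <- info$snp_id
  structure(list(info = info, dosage = dosage), class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set: ", nrow(x$info), " SNPs x ", ncol(x$dosage), " samples, ",
      sum(is.na(x$dosage)), " missing calls\n", sep = "")
  invisible(x)
}

#' Gene regions with cis windows
#'
#' Attaches the testing window (gene body extended by `window` bp on both
#' sides, clipped at position 1) to a table of gene coordinates
#' (1-based, inclusive).
#'
#' @param regions Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window Flank size in bp (default 5000).
#' @return The input with `window_start`, `window_end` columns; class
#'   `gene_regions`.
#' @export
gene_regions <- function(regions, window = 5000) {
  stopifnot(is.data.frame(regions),
            all(c("gene_id", "chrom", "start", "end") %in% names(regions)),
            window >= 0)
  if (any(regions$start > regions$end)) stop("start must be <= end")
  if (any(regions$start < 1)) stop("start must be >= 1")
  regions$window_start <- pmax(regions$start - window, 1)
  regions$window_end <- regions$end + window
  class(regions) <- c("gene_regions", "data.frame")
  regions
}

#' Retain testable SNPs near a gene
#'
#' Keeps SNPs on the gene's chromosome whose position falls inside the cis
#' window, with at least two distinct observed dosages, and whose minor
#' allele is carried (dosage 1 or 2) by at least `min_minor_samples`
#' non-missing samples.
#'
#' @param snps A [snp_set()].
#' @param region One row of a [gene_regions()] table.
#' @param min_minor_samples Minimum number of carrier samples (default 5).
#' @return A `snp_set` with the retained SNPs, ordered by position.
#' @export
filter_snps <- function(snps, region, min_minor_samples = 5) {
  stopifnot(inherits(snps, "snp_set"))
  in_win <- snps$info$chrom == region$chrom &
    snps$info$pos >= region$window_start &
    snps$info$pos <= region$window_end
  keep <- which(in_win)
  if (length(keep) > 0) {
    ok <- vapply(keep, function(s) {
      d <- snps$dosage[s, ]
      d <- d[!is.na(d)]
      length(unique(d)) >= 2 && sum(d >= 1) >= min_minor_samples
    }, logical(1))
    keep <- keep[ok]
  }
  keep <- keep[order(snps$info$pos[keep], snps$info$snp_id[keep])]
  snp_set(snps$info[keep, , drop = FALSE],
          snps$dosage[keep, , drop = FALSE])
}

#' Group SNPs with identical genotype vectors into blocks
#'
#' SNPs sharing an identical dosage vector (including the missingness
#' pattern) define the same grouping of samples, hence the same model; each
#' such block is tested once. Blocks are ordered by their leftmost member.
#'
#' @param snps A [snp_set()] of retained SNPs.
#' @param gene_id Gene identifier used to label blocks.
#' @return List of blocks, each a list with `block_id`, `snp_ids`,
#'   `genotypes` (the shared dosage vector, named by sample).
#' @export
block_snps <- function(snps, gene_id) {
  stopifnot(inherits(snps, "snp_set"))
  if (nrow(snps$info) == 0) return(list())
  key <- apply(snps$dosage, 1, function(d)
    paste(ifelse(is.na(d), ".", d), collapse = ""))
  idx <- split(seq_len(nrow(snps$info)), key)
  firstpos <- vapply(idx, function(i) min(snps$info$pos[i]), numeric(1))
  idx <- idx[order(firstpos)]
  lapply(seq_along(idx), function(b) {
    i <- idx[[b]]
    list(block_id = sprintf("%s.block%d", gene_id, b),
         snp_ids = snps$info$snp_id[i],
         genotypes = snps$dosage[i[1], ])
  })
}

#' Likelihood-ratio test of usage against genotype groups
#'
#' Groups samples by minor-allele dosage (unordered categories) and runs the
#' equal-proportions LRT at a fixed gene-level concentration. Samples with
#' missing dosage are excluded for this block; blocks with fewer than two
#' observed dosage groups are skipped (`NULL` with attribute `reason`).
#'
#' @param gene A [gene_counts()] object.
#' @param block One block from [block_snps()].
#' @param gamma_plus Gene-level concentration.
#' @return One-row data frame (`block_id`, `lr`, `df`, `pvalue`, ...), or
#'   `NULL` when the block is untestable.
#' @export
test_block <- function(gene, block, gamma_plus) {
  d <- block$genotypes[colnames(gene$counts)]
  use <- !is.na(d)
  if (sum(use) < 2 || length(unique(d[use])) < 2)
    return(NULL)  # fewer than 2 dosage groups: untestable
  sub <- gene_counts(gene$gene_id, gene$counts[, use, drop = FALSE])
  grouping <- factor(d[use])
  fits <- fit_full_and_null(sub, grouping, gamma_plus)
  row <- lrt(sub, fits$full, fits$null, nlevels(grouping))
  row$block_id <- block$block_id
  row$snp_ids <- paste(block$snp_ids, collapse = ",")
  row$n_groups <- nlevels(grouping)
  row
}

# Nominal block p-values for one gene, given blocks and a concentration;
# columns of `counts_order` permute the samples (permutation null).
.gene_block_pvalues <- function(gene, blocks, gamma_plus, perm = NULL) {
  counts <- gene$counts
  if (!is.null(perm)) {
    counts <- counts[, perm, drop = FALSE]
    colnames(counts) <- colnames(gene$counts)
  }
  gperm <- gene_counts(gene$gene_id, counts)
  vapply(blocks, function(b) {
    row <- test_block(gperm, b, gamma_plus)
    if (is.null(row)) NA_real_ else row$pvalue
  }, numeric(1))
}

#' Permutation adjustment of per-gene association p-values
#'
#' Re-tests all blocks of a gene on datasets in which the sample labels of
#' the counts are permuted (genotypes fixed), recording the minimum nominal
#' p-value per permutation. The per-gene adjusted p-value is
#' `(1 + #\{permutation minima <= observed minimum\}) / (1 + n_permutations)`.
#' Per-block empirical p-values against the pooled permutation null (all
#' block p-values from all permutations) are also returned.
#'
#' @param gene A [gene_counts()] object.
#' @param blocks Blocks from [block_snps()].
#' @param gamma_plus Gene-level concentration.
#' @param observed_p Nominal per-block p-values for the observed data.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed (per-gene substreams are derived from it and the
#'   gene id, so results do not depend on gene order).
#' @return List with `adjusted_p` (scalar), `block_empirical_p` (per
#'   block), and `perm_min_p` (the permutation minima).
#' @export
permutation_adjust <- function(gene, blocks, gamma_plus, observed_p,
                               n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  n <- ncol(gene$counts)
  gene_key <- sum(utf8ToInt(gene$gene_id))
  perm_min <- numeric(n_permutations)
  pool <- vector("list", n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(.substream_seed(seed, gene_key, b))
    perm <- sample.int(n)
    pb <- .gene_block_pvalues(gene, blocks, gamma_plus, perm = perm)
    perm_min[b] <- suppressWarnings(min(pb, na.rm = TRUE))
    pool[[b]] <- pb
  }
  obs_min <- suppressWarnings(min(observed_p, na.rm = TRUE))
  adjusted <- (1 + sum(perm_min <= obs_min)) / (1 + n_permutations)
  pool <- unlist(pool)
  pool <- pool[!is.na(pool)]
  block_emp <- vapply(observed_p, function(p)
    if (is.na(p)) NA_real_ else (1 + sum(pool <= p)) / (1 + length(pool)),
    numeric(1))
  list(adjusted_p = adjusted, block_empirical_p = block_emp,
       perm_min_p = perm_min)
}

#' Transcript-usage QTL scan
#'
#' For each gene: retain nearby testable SNPs ([filter_snps()]), collapse
#' identical genotype vectors into blocks ([block_snps()]), test each block
#' with the equal-proportions LRT at a gene-level concentration estimated
#' once from the whole cohort (no grouping), and adjust the per-gene minimum
#' p-value by permutation. BH correction is then applied across genes on the
#' permutation-adjusted p-values.
#'
#' Samples are matched between counts and genotypes by id and analyzed in
#' sorted id order, and SNPs in position order, so results do not depend on
#' input ordering.
#'
#' @param data A [dm_data()] dataset (pre-filtered).
#' @param snps A [snp_set()].
#' @param regions A [gene_regions()] table.
#' @param config [dispersion_config()] for the cohort-level concentration.
#' @param gamma_plus Optional known concentration (scalar or named by gene)
#'   bypassing estimation.
#' @param min_minor_samples Carrier threshold for [filter_snps()].
#' @param n_permutations Permutations per gene.
#' @param seed Integer seed for the permutations.
#' @return Data frame of class `dm_tuqtl`, one row per tested block:
#'   `gene_id`, `block_id`, `snp_ids`, `n_groups`, `lr`, `df`, `pvalue`,
#'   `block_empirical_p`, `gene_adj_pvalue`, `gene_bh_adj_pvalue`. The
#'   `skipped` attribute lists genes without testable blocks.
#' @export
run_tuqtl <- function(data, snps, regions, config = dispersion_config(),
                      gamma_plus = NULL, min_minor_samples = 5,
                      n_permutations = 100, seed = 1) {
  stopifnot(inherits(data, "dm_data"), inherits(snps, "snp_set"),
            inherits(regions, "data.frame"))
  shared <- intersect(dm_samples(data), colnames(snps$dosage))
  if (length(shared) == 0)
    stop("no samples shared between counts and genotypes")
  shared <- sort(shared)
  data <- .reorder_samples(data, shared)
  snps <- snp_set(snps$info, snps$dosage[, shared, drop = FALSE])
  # gene-level concentration from the whole cohort, single group
  one_group <- stats::setNames(rep("all", length(shared)), shared)
  if (is.null(gamma_plus)) {
    disp <- dm_dispersion(data, one_group, config)
    gp_by_gene <- stats::setNames(disp$gamma_plus, disp$gene_id)
  } else if (length(gamma_plus) == 1L) {
    gp_by_gene <- stats::setNames(rep(gamma_plus, length(data)), names(data))
  } else {
    gp_by_gene <- gamma_plus
  }
  rows <- list()
  skipped <- data.frame(gene_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  gene_adj <- c()
  for (gid in names(data)) {
    gene <- data[[gid]]
    r <- regions[regions$gene_id == gid, , drop = FALSE]
    if (nrow(r) == 0) {
      skipped <- rbind(skipped, data.frame(gene_id = gid,
                                           reason = "no region"))
      next
    }
    kept <- filter_snps(snps, r[1, ], min_minor_samples)
    blocks <- block_snps(kept, gid)
    res <- if (length(blocks) > 0)
      lapply(blocks, test_block, gene = gene, gamma_plus = gp_by_gene[[gid]])
    else list()
    ok <- !vapply(res, is.null, logical(1))
    blocks <- blocks[ok]
    res <- res[ok]
    if (length(res) == 0) {
      skipped <- rbind(skipped, data.frame(gene_id = gid,
                                           reason = "no testable SNP block"))
      next
    }
    tab <- do.call(rbind, res)
    tab$gene_id <- gid
    pa <- permutation_adjust(gene, blocks, gp_by_gene[[gid]], tab$pvalue,
                             n_permutations = n_permutations, seed = seed)
    tab$block_empirical_p <- pa$block_empirical_p
    tab$gene_adj_pvalue <- pa$adjusted_p
    gene_adj[gid] <- pa$adjusted_p
    rows[[gid]] <- tab
  }
  if (length(rows) == 0) {
    out <- data.frame(gene_id = character(0), block_id = character(0),
                      snp_ids = character(0), n_groups = integer(0),
                      lr = numeric(0), df = integer(0), pvalue = numeric(0),
                      block_empirical_p = numeric(0),
                      gene_adj_pvalue = numeric(0),
                      gene_bh_adj_pvalue = numeric(0))
    return(structure(out, skipped = skipped,
                     class = c("dm_tuqtl", "data.frame")))
  }
  bh <- stats::setNames(adjust_bh(unname(gene_adj)), names(gene_adj))
  out <- do.call(rbind, rows)
  out$gene_bh_adj_pvalue <- bh[out$gene_id]
  out <- out[, c("gene_id", "block_id", "snp_ids", "n_groups", "lr", "df",
                 "pvalue", "block_empirical_p", "gene_adj_pvalue",
                 "gene_bh_adj_pvalue")]
  rownames(out) <- NULL
  structure(out, skipped = skipped, class = c("dm_tuqtl", "data.frame"))
}

#' @export
print.dm_tuqtl <- function(x, ...) {
  ng <- length(unique(x$gene_id))
  cat("dm_tuqtl: ", nrow(x), " blocks across ", ng, " genes; ",
      sum(!duplicated(x$gene_id) & x$gene_bh_adj_pvalue <= 0.05, na.rm = TRUE),
      " genes at BH-adjusted p <= 0.05\n", sep = "")
  print.data.frame(utils::head(x[order(x$pvalue), ], 6))
  invisible(x)
}
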