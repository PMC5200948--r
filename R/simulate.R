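# Per-gene seed substreams: draws for gene g do not depend on how many genes
# precede it, so subsetting or reordering genes leaves their data unchanged.
.substream_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807 +
                as.double(j) * 69621) %% 2147483647)
}

#' Geometrically decaying proportion vector
#'
#' `pi_j` proportional to `rate^(j-1)`, normalized; models genes dominated
#' by one isoform with a decaying tail of minor isoforms.
#'
#' @param q Number of features (>= 2).
#' @param rate Decay ratio in (0, 1); default 0.5.
#' @return Proportion vector, strictly decreasing, summing to 1.
#' @export
decaying_proportions <- function(q, rate = 0.5) {
  stopifnot(q >= 2, rate > 0, rate < 1)
  p <- rate^(seq_len(q) - 1)
  p / sum(p)
}

.make_proportions <- function(proportions, q) {
  if (is.character(proportions)) {
    switch(match.arg(proportions, c("uniform", "decaying")),
           uniform = rep(1 / q, q),
           decaying = decaying_proportions(q))
  } else {
    .check_simplex(proportions)
    if (length(proportions) != q) stop("'proportions' must have length q")
    proportions
  }
}

.draw_gene <- function(m, pi_by_group, gamma_plus, n_per_group, groups) {
  cols <- lapply(seq_along(groups), function(k)
    rdirmnom(n_per_group[k], m, pi_by_group[[k]], gamma_plus))
  do.call(cbind, cols)
}

#' Simulate a null Dirichlet-multinomial dataset
#'
#' Two-group data with identical parameters in both groups: for every gene
#' and sample, proportions are drawn from Dirichlet(`gamma_plus * pi0`) and
#' counts from Multinomial(`m`, proportions). Defaults follow the
#' small-sample calibration design: expression 1000, 3 features, 3 vs 3.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group; a scalar (both groups) or length-2
#'   vector.
#' @param m Per-gene, per-sample total count.
#' @param q Features per gene.
#' @param proportions `"uniform"`, `"decaying"`, or an explicit simplex
#'   vector of length `q`.
#' @param gamma_plus Common concentration (scalar), used for every gene when
#'   `dispersion = "common"`.
#' @param dispersion `"common"` (all genes share `gamma_plus`) or
#'   `"genewise"` (per-gene log10 concentration drawn uniformly over
#'   `genewise_log10_range`).
#' @param genewise_log10_range Range for the genewise architecture.
#' @param seed Integer seed; every gene uses a substream derived from it.
#' @return List of class `dm_sim`: `data` ([dm_data()]), `group` (named
#'   factor), and `truth` (per-gene data frame with `gamma_plus`, `ds`
#'   status and the generating proportions as a matrix attribute).
#' @examples
#' sim <- simulate_null(n_genes = 3, m = 100, q = 3, gamma_plus = 20, seed = 1)
#' sim$truth
#' @export
simulate_null <- function(n_genes = 1000, n_per_group = 3, m = 1000, q = 3,
                          proportions = "uniform", gamma_plus = 100,
                          dispersion = c("common", "genewise"),
                          genewise_log10_range = c(1, 3), seed = 1) {
  simulate_dtu(n_genes = n_genes, n_per_group = n_per_group, m = m, q = q,
               proportions = proportions, gamma_plus = gamma_plus,
               dispersion = match.arg(dispersion),
               genewise_log10_range = genewise_log10_range,
               switch_fraction = 0, seed = seed)
}

#' Simulate a dataset with differential transcript usage
#'
#' As [simulate_null()], but a fraction of genes is differential: in the
#' second group the two largest entries of the proportion vector are
#' swapped (an isoform switch of the two most abundant features). Genes
#' whose top two proportions are tied have a no-op swap and are relabelled
#' null in the truth table.
#'
#' @inheritParams simulate_null
#' @param switch_fraction Fraction of genes carrying the switch (the first
#'   `round(switch_fraction * n_genes)` genes).
#' @return A `dm_sim` list; `truth$ds` flags the truly differential genes.
#' @export
simulate_dtu <- function(n_genes = 1000, n_per_group = 3, m = 1000, q = 3,
                         proportions = "uniform", gamma_plus = 100,
                         dispersion = c("common", "genewise"),
                         genewise_log10_range = c(1, 3),
                         switch_fraction = 0.1, seed = 1) {
  dispersion <- match.arg(dispersion)
  stopifnot(n_genes >= 1, m >= q, q >= 2, gamma_plus > 0,
            switch_fraction >= 0, switch_fraction <= 1)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2)
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1))
  pi0 <- .make_proportions(proportions, q)
  groups <- c("A", "B")
  sample_ids <- paste0(rep(groups, n_per_group),
                       c(seq_len(n_per_group[1]), seq_len(n_per_group[2])))
  group <- stats::setNames(factor(rep(groups, n_per_group)), sample_ids)
  n_ds <- round(switch_fraction * n_genes)
  top2 <- order(pi0, decreasing = TRUE)[1:2]
  pi_alt <- pi0
  pi_alt[top2] <- pi0[rev(top2)]
  tied <- isTRUE(all.equal(pi0[top2[1]], pi0[top2[2]]))
  genes <- vector("list", n_genes)
  gp_true <- numeric(n_genes)
  ds <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    set.seed(.substream_seed(seed, g))
    gp <- if (dispersion == "genewise")
      10^stats::runif(1, genewise_log10_range[1], genewise_log10_range[2])
    else gamma_plus
    is_ds <- g <= n_ds && !tied
    piB <- if (g <= n_ds) pi_alt else pi0
    y <- .draw_gene(m, list(pi0, piB), gp, n_per_group, groups)
    colnames(y) <- sample_ids
    rownames(y) <- paste0("f", seq_len(q))
    genes[[g]] <- gene_counts(sprintf("g%04d", g), y)
    gp_true[g] <- gp
    ds[g] <- is_ds
  }
  truth <- data.frame(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
                      gamma_plus = gp_true, ds = ds,
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(truth, "pi_null") <- pi0
  attr(truth, "pi_alt") <- pi_alt
  structure(list(data = dm_data(genes), group = group, truth = truth),
            class = "dm_sim")
}

#' @export
print.dm_sim <- function(x, ...) {
  cat("dm_sim: ", length(x$data), " genes, ",
      length(x$group), " samples (", paste(table(x$group), collapse = " vs "),
      "), ", sum(x$truth$ds), " differential\n", sep = "")
  invisible(x)
}

#' Simulate bi-allelic SNP genotypes
#'
#' Independent Hardy-Weinberg genotypes (minor-allele dosage 0/1/2) for a
#' set of SNP positions, optionally with missing calls.
#'
#' @param n_snps Number of SNPs.
#' @param sample_ids Character vector of sample ids.
#' @param maf Minor-allele frequency (scalar or per-SNP vector).
#' @param chrom Chromosome name.
#' @param positions 1-based positions (default: evenly spread 1..n_snps*500).
#' @param missing_rate Fraction of calls set missing.
#' @param seed Integer seed.
#' @return A `snp_set` (see [read_genotypes()]).
#' @export
simulate_genotypes <- function(n_snps, sample_ids, maf = 0.3, chrom = "chr1",
                               positions = NULL, missing_rate = 0, seed = 1) {
  stopifnot(n_snps >= 1, length(sample_ids) >= 1)
  set.seed(.substream_seed(seed, 0L, 7L))
  if (is.null(positions)) positions <- seq_len(n_snps) * 500L
  maf <- rep_len(maf, n_snps)
  dosage <- t(vapply(seq_len(n_snps), function(s)
    stats::rbinom(length(sample_ids), 2, maf[s]), numeric(length(sample_ids))))
  if (missing_rate > 0)
    dosage[stats::runif(length(dosage)) < missing_rate] <- NA
  dimnames(dosage) <- list(paste0("snp", seq_len(n_snps)), sample_ids)
  snp_set(data.frame(snp_id = rownames(dosage), chrom = chrom,
                     pos = as.integer(positions),
                     stringsAsFactors = FALSE),
          dosage)
}

#' Simulate a transcript-usage QTL dataset
#'
#' Counts, genotypes and gene regions for a tuQTL scan. Genotypes are drawn
#' independently of the counts (a global null) except for the first
#' `n_qtl` genes, where carriers of the minor allele of a designated causal
#' SNP have the two most abundant features swapped - a strong usage QTL.
#'
#' @inheritParams simulate_dtu
#' @param n_samples Number of samples.
#' @param n_snps_per_gene SNPs simulated in each gene's window.
#' @param n_qtl Number of genes given a genuine dosage-linked switch.
#' @param maf Minor-allele frequency of the simulated SNPs.
#' @return List of class `dm_sim_tuqtl`: `data`, `snps`, `regions`, `truth`.
#' @export
simulate_tuqtl <- function(n_genes = 100, n_samples = 30, m = 1000, q = 3,
                           proportions = "decaying", gamma_plus = 100,
                           n_snps_per_gene = 6, n_qtl = 0, maf = 0.3,
                           seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 2, q >= 2, n_qtl <= n_genes)
  pi0 <- .make_proportions(proportions, q)
  top2 <- order(pi0, decreasing = TRUE)[1:2]
  pi_alt <- pi0
  pi_alt[top2] <- pi0[rev(top2)]
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  gene_len <- 2000L
  gap <- 20000L
  genes <- vector("list", n_genes)
  snp_info <- vector("list", n_genes)
  snp_dos <- vector("list", n_genes)
  causal <- character(n_genes)
  for (g in seq_len(n_genes)) {
    start <- (g - 1L) * gap + 10001L
    set.seed(.substream_seed(seed, g, 1L))
    pos <- sort(sample(seq(start - 5000L, start + gene_len + 5000L),
                       n_snps_per_gene))
    dos <- t(vapply(seq_len(n_snps_per_gene), function(s)
      stats::rbinom(n_samples, 2, maf), numeric(n_samples)))
    ids <- sprintf("g%04d_snp%d", g, seq_len(n_snps_per_gene))
    dimnames(dos) <- list(ids, sample_ids)
    snp_info[[g]] <- data.frame(snp_id = ids, chrom = "chr1", pos = pos,
                                stringsAsFactors = FALSE)
    snp_dos[[g]] <- dos
    set.seed(.substream_seed(seed, g, 2L))
    if (g <= n_qtl) {
      causal[g] <- ids[1]
      carrier <- dos[1, ] >= 1
      y <- matrix(0, q, n_samples)
      for (i in seq_len(n_samples))
        y[, i] <- rdirmnom(1, m, if (carrier[i]) pi_alt else pi0,
                           gamma_plus)[, 1]
    } else {
      y <- rdirmnom(n_samples, m, pi0, gamma_plus)
    }
    dimnames(y) <- list(paste0("f", seq_len(q)), sample_ids)
    genes[[g]] <- gene_counts(sprintf("g%04d", g), y)
  }
  regions <- gene_regions(data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = "chr1",
    start = (seq_len(n_genes) - 1L) * gap + 10001L,
    end = (seq_len(n_genes) - 1L) * gap + 10000L + gene_len,
    stringsAsFactors = FALSE))
  snps <- snp_set(do.call(rbind, snp_info), do.call(rbind, snp_dos))
  truth <- data.frame(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
                      qtl = seq_len(n_genes) <= n_qtl,
                      causal_snp = ifelse(causal == "", NA, causal),
                      stringsAsFactors = FALSE)
  structure(list(data = dm_data(genes), snps = snps, regions = regions,
                 truth = truth), class = "dm_sim_tuqtl")
}

#' Type-I error and discovery-rate summaries against simulated truth
#'
#' The false-positive rate is the fraction of truly null genes with nominal
#' p-value at or below `p_threshold`. True-positive rate and achieved false
#' discovery rate are computed on the BH-adjusted p-values at each of
#' `thresholds` (achieved FDR is 0 when nothing is called).
#'
#' @param results Data frame with `gene_id`, `pvalue`, `adj_pvalue`
#'   (e.g. a [dm_test()] table).
#' @param truth Data frame with `gene_id` and logical `ds`.
#' @param thresholds Adjusted-p thresholds for TPR/FDR.
#' @param p_threshold Nominal threshold for the FP rate.
#' @return List with `fp_rate`, `power` (TPR at the middle threshold), and
#'   `table` (threshold, n_called, tpr, fdr).
#' @export
evaluate_calibration <- function(results, truth,
                                 thresholds = c(0.01, 0.05, 0.1),
                                 p_threshold = 0.05) {
  if (!all(c("gene_id", "pvalue", "adj_pvalue") %in% names(results)))
    stop("'results' must have gene_id, pvalue, adj_pvalue")
  i <- match(results$gene_id, truth$gene_id)
  if (any(is.na(i))) stop("results and truth are misaligned")
  ds <- truth$ds[i]
  nullp <- results$pvalue[!ds]
  fp_rate <- if (length(nullp) > 0) mean(nullp <= p_threshold, na.rm = TRUE)
             else NA_real_
  tab <- do.call(rbind, lapply(thresholds, function(t) {
    called <- !is.na(results$adj_pvalue) & results$adj_pvalue <= t
    tp <- sum(called & ds)
    fp <- sum(called & !ds)
    data.frame(threshold = t, n_called = tp + fp,
               tpr = if (any(ds)) tp / sum(ds) else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
  }))
  mid <- which.min(abs(thresholds - stats::median(thresholds)))
  list(fp_rate = fp_rate, power = tab$tpr[mid], table = tab)
}

#' Error summaries of concentration estimates
#'
#' Median absolute and median raw (signed) errors of the estimated
#' concentration, on both the natural and the log10 scale.
#'
#' @param estimates Data frame with `gene_id`, `gamma_plus` (e.g. a
#'   `dm_dispersion` table).
#' @param truth Data frame with `gene_id`, `gamma_plus` (true values).
#' @return One-row data frame: `median_abs_error`, `median_raw_error`,
#'   `median_abs_error_log10`, `median_raw_error_log10`.
#' @export
estimator_error <- function(estimates, truth) {
  i <- match(estimates$gene_id, truth$gene_id)
  if (any(is.na(i))) stop("estimates and truth are misaligned")
  err <- estimates$gamma_plus - truth$gamma_plus[i]
  lerr <- log10(estimates$gamma_plus) - log10(truth$gamma_plus[i])
  data.frame(median_abs_error = stats::median(abs(err)),
             median_raw_error = stats::median(err),
             median_abs_error_log10 = stats::median(abs(lerr)),
             median_raw_error_log10 = stats::median(lerr))
}
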