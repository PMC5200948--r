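make_snps <- function(pos, dosage, ids = paste0("snp", seq_along(pos)),
                      chrom = "chr1") {
  snp_set(data.frame(snp_id = ids, chrom = chrom, pos = pos,
                     stringsAsFactors = FALSE), dosage)
}

test_that("SNP retention honors the cis window exactly", {
  region <- gene_regions(data.frame(gene_id = "g1", chrom = "chr1",
                                    start = 10000, end = 12000))[1, ]
  n <- 12
  dos <- matrix(rep(c(0, 1), each = 6), 4, n, byrow = TRUE,
                dimnames = list(NULL, paste0("s", 1:n)))
  snps <- make_snps(c(5000, 4999, 17000, 17001), dos)
  kept <- filter_snps(snps, region, min_minor_samples = 5)
  expect_setequal(kept$info$snp_id, c("snp1", "snp3"))
})

test_that("SNP retention enforces carriers and polymorphism", {
  region <- gene_regions(data.frame(gene_id = "g1", chrom = "chr1",
                                    start = 1000, end = 2000))[1, ]
  n <- 10
  five <- c(rep(1, 5), rep(0, 5))
  four <- c(rep(1, 4), rep(0, 6))
  mono <- rep(0, n)
  with_na <- c(rep(1, 5), 0, 0, NA, NA, NA)
  dos <- rbind(five, four, mono, with_na)
  colnames(dos) <- paste0("s", 1:n)
  snps <- make_snps(rep(1500, 4), dos)
  kept <- filter_snps(snps, region, min_minor_samples = 5)
  expect_setequal(kept$info$snp_id, c("snp1", "snp4"))
  # but snp4 fails if one of its carriers goes missing
  dos2 <- dos
  dos2[4, 1] <- NA
  kept2 <- filter_snps(make_snps(rep(1500, 4), dos2), region, 5)
  expect_setequal(kept2$info$snp_id, "snp1")
})

test_that("blocking partitions SNPs exactly by genotype vector", {
  n <- 6
  v1 <- c(0, 1, 2, 0, 1, 0)
  v2 <- c(1, 1, 0, 0, 2, 2)
  dos <- rbind(v1, v2, v1)
  colnames(dos) <- paste0("s", 1:n)
  blocks <- block_snps(make_snps(c(100, 200, 300), dos), "g1")
  expect_length(blocks, 2)
  expect_setequal(blocks[[1]]$snp_ids, c("snp1", "snp3"))
  expect_equal(blocks[[2]]$snp_ids, "snp2")
  # all distinct -> one block each
  dos2 <- rbind(c(0, 0, 0, 1, 1, 1), c(1, 1, 1, 0, 0, 0), c(0, 1, 0, 1, 0, 1))
  colnames(dos2) <- paste0("s", 1:n)
  expect_length(block_snps(make_snps(1:3 * 100, dos2), "g1"), 3)
  # random matrix vs O(n^2) pairwise-equality oracle
  set.seed(71)
  dosr <- matrix(sample(c(0, 1, 2, NA), 20 * 8, replace = TRUE), 20, 8)
  colnames(dosr) <- paste0("s", 1:8)
  blocks_r <- block_snps(make_snps(seq_len(20) * 10, dosr,
                                   ids = paste0("r", 1:20)), "g")
  # oracle partition
  same <- function(a, b) identical(ifelse(is.na(a), -1, a),
                                   ifelse(is.na(b), -1, b))
  groups <- list()
  for (s in seq_len(20)) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (same(dosr[groups[[k]][1], ], dosr[s, ])) {
        groups[[k]] <- c(groups[[k]], s)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- s
  }
  expect_length(blocks_r, length(groups))
  got <- lapply(blocks_r, function(b) sort(b$snp_ids))
  want <- lapply(groups, function(g) sort(paste0("r", g)))
  expect_setequal(got, want)
})

test_that("testing per SNP equals testing per block", {
  tq <- simulate_tuqtl(n_genes = 3, n_samples = 20, n_snps_per_gene = 4,
                       seed = 72)
  gene <- tq$data[[1]]
  region <- tq$regions[tq$regions$gene_id == gene$gene_id, ]
  kept <- filter_snps(tq$snps, region, min_minor_samples = 3)
  blocks <- block_snps(kept, gene$gene_id)
  for (b in blocks) {
    pb <- test_block(gene, b, 100)
    for (s in b$snp_ids) {
      single <- list(block_id = s, snp_ids = s,
                     genotypes = kept$dosage[s, ])
      ps <- test_block(gene, single, 100)
      expect_equal(ps$pvalue, pb$pvalue)
      expect_equal(ps$lr, pb$lr)
    }
  }
  # dosage groups set the degrees of freedom: (c-1)(q-1)
  nlev <- vapply(blocks, function(b)
    length(unique(b$genotypes[!is.na(b$genotypes)])), integer(1))
  res <- lapply(blocks, test_block, gene = gene, gamma_plus = 100)
  expect_equal(vapply(res, `[[`, numeric(1), "df"), (nlev - 1) * 2)
})

test_that("constant and missing-heavy blocks are skipped", {
  gene <- random_gene(q = 3, n = 6, seed = 73)
  same <- list(block_id = "b", snp_ids = "s",
               genotypes = stats::setNames(rep(1, 6), colnames(gene$counts)))
  expect_null(test_block(gene, same, 50))
  onena <- list(block_id = "b", snp_ids = "s",
                genotypes = stats::setNames(c(0, NA, NA, NA, NA, NA),
                                            colnames(gene$counts)))
  expect_null(test_block(gene, onena, 50))
})

test_that("permutation adjustment follows the +1 smoothed formula", {
  tq <- simulate_tuqtl(n_genes = 2, n_samples = 16, n_snps_per_gene = 3,
                       n_qtl = 1, gamma_plus = 100, seed = 74)
  gene <- tq$data[[1]]  # strong QTL: observed min p far below any permutation
  region <- tq$regions[1, ]
  kept <- filter_snps(tq$snps, region, min_minor_samples = 3)
  blocks <- block_snps(kept, gene$gene_id)
  obs <- vapply(blocks, function(b) test_block(gene, b, 100)$pvalue,
                numeric(1))
  pa <- permutation_adjust(gene, blocks, 100, obs, n_permutations = 19,
                           seed = 5)
  expect_equal(pa$adjusted_p, 1 / 20)
  # observed minimum of 1 can never beat a permutation: adjusted p is 1
  pa1 <- permutation_adjust(gene, blocks, 100, rep(1, length(blocks)),
                            n_permutations = 19, seed = 5)
  expect_equal(pa1$adjusted_p, 1)
  expect_error(permutation_adjust(gene, blocks, 100, obs, 0, 1), "permut")
})

test_that("the scan is reproducible and order-invariant", {
  tq <- simulate_tuqtl(n_genes = 4, n_samples = 20, n_snps_per_gene = 3,
                       seed = 75)
  res1 <- run_tuqtl(tq$data, tq$snps, tq$regions, gamma_plus = 100,
                    min_minor_samples = 3, n_permutations = 5, seed = 11)
  res2 <- run_tuqtl(tq$data, tq$snps, tq$regions, gamma_plus = 100,
                    min_minor_samples = 3, n_permutations = 5, seed = 11)
  expect_equal(res1, res2)
  # shuffle SNP rows and sample columns
  sperm <- rev(seq_len(nrow(tq$snps$info)))
  snps_r <- snp_set(tq$snps$info[sperm, ], tq$snps$dosage[sperm, ])
  ids <- rev(colnames(tq$snps$dosage))
  snps_r <- snp_set(snps_r$info, snps_r$dosage[, ids])
  res3 <- run_tuqtl(tq$data, snps_r, tq$regions, gamma_plus = 100,
                    min_minor_samples = 3, n_permutations = 5, seed = 11)
  expect_equal(res1, res3)
  # nominal p-values do not depend on the permutation count
  res4 <- run_tuqtl(tq$data, tq$snps, tq$regions, gamma_plus = 100,
                    min_minor_samples = 3, n_permutations = 10, seed = 11)
  expect_equal(res4$pvalue, res1$pvalue)
})

test_that("genes without testable SNPs yield a clean empty result", {
  tq <- simulate_tuqtl(n_genes = 2, n_samples = 10, n_snps_per_gene = 2,
                       seed = 76)
  res <- run_tuqtl(tq$data, tq$snps, tq$regions, gamma_plus = 100,
                   min_minor_samples = 11, n_permutations = 3, seed = 1)
  expect_equal(nrow(res), 0)
  expect_equal(nrow(attr(res, "skipped")), 2)
  # disjoint samples are an error
  bad <- snp_set(tq$snps$info,
                 `colnames<-`(tq$snps$dosage,
                              paste0("x", seq_len(ncol(tq$snps$dosage)))))
  expect_error(run_tuqtl(tq$data, bad, tq$regions), "shared")
})

test_that("a dosage-linked usage switch is ranked first", {
  tq <- simulate_tuqtl(n_genes = 12, n_samples = 30, n_qtl = 1,
                       gamma_plus = 100, seed = 77)
  res <- run_tuqtl(tq$data, tq$snps, tq$regions, gamma_plus = 100,
                   n_permutations = 30, seed = 3)
  per_gene <- res[!duplicated(res$gene_id), ]
  best <- per_gene$gene_id[which.min(per_gene$gene_adj_pvalue)]
  expect_equal(best, tq$truth$gene_id[tq$truth$qtl][1])
})
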