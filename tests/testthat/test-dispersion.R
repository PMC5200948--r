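test_that("profile likelihood is a maximum over proportions", {
  # symmetric two-feature counts: the profiled proportions are (0.5, 0.5)
  y <- matrix(c(4, 4, 6, 6), 2, 2, dimnames = list(c("f1", "f2"),
                                                   c("s1", "s2")))
  gene <- gene_counts("g", y)
  pl <- profile_loglik(gene, rep("A", 2), 15)
  direct <- gene_log_likelihood(gene, rep("A", 2),
                                matrix(c(0.5, 0.5), 2,
                                       dimnames = list(NULL, "A")), 15)
  expect_equal(as.numeric(pl), direct, tolerance = 1e-8)
  # PL dominates the likelihood at arbitrary fixed proportions
  gene2 <- random_gene(q = 3, n = 4, seed = 3)
  pl2 <- profile_loglik(gene2, rep("A", 4), 40)
  set.seed(1)
  for (i in 1:5) {
    p <- rexp(3) + 0.05
    p <- p / sum(p)
    expect_gte(as.numeric(pl2) + 1e-9,
               gene_log_likelihood(gene2, rep("A", 4),
                                   matrix(p, 3, dimnames = list(NULL, "A")),
                                   40))
  }
  # and matches a dense simplex grid search
  best <- simplex_grid_best(gene2$counts, 40, n = 200) +
    dmusage:::.dm_const_terms(gene2$counts, 40)
  expect_equal(as.numeric(pl2), best, tolerance = 1e-3)
  expect_gte(as.numeric(pl2), best - 1e-6)
})

test_that("analytic observed information matches finite differences", {
  gene <- random_gene(q = 2, n = 5, m = 200, gamma_plus = 20, seed = 9)
  gp <- 25
  fit <- estimate_proportions(gene, rep("A", 5), gp)
  p1 <- fit$proportions[1, "A"]
  f <- function(p) loglik_terms_oracle(gene$counts, c(p, 1 - p), gp)
  h <- 1e-5
  fd_info <- -(f(p1 + h) - 2 * f(p1) + f(p1 - h)) / h^2
  logdet <- dmusage:::.obs_info_logdet(gene$counts, fit$proportions[, "A"], gp)
  expect_equal(logdet, log(fd_info), tolerance = 1e-4)
})

test_that("information grows with data and defines the CR penalty", {
  gene <- random_gene(q = 3, n = 3, seed = 4)
  doubled <- gene_counts("g1", cbind(gene$counts,
                                     `colnames<-`(gene$counts,
                                                  paste0("d", 1:3))))
  a1 <- adjusted_profile_loglik(gene, rep("A", 3), 30)
  a2 <- adjusted_profile_loglik(doubled, rep("A", 6), 30)
  expect_gt(attr(a2, "logdet"), attr(a1, "logdet"))
  # APL = PL - logdet/2 by definition
  expect_equal(as.numeric(a1), attr(a1, "pl") - attr(a1, "logdet") / 2)
  expect_false(attr(a1, "fallback"))
})

test_that("degenerate data falls back to the raw profile likelihood", {
  # two features never observed: the information matrix is singular
  y <- matrix(c(5, 0, 0, 7, 0, 0), 3, 2, dimnames = list(paste0("f", 1:3),
                                                         c("s1", "s2")))
  gene <- gene_counts("g", y)
  a <- adjusted_profile_loglik(gene, rep("A", 2), 10)
  expect_true(attr(a, "fallback"))
  expect_equal(as.numeric(a), attr(a, "pl"))
})

test_that("common estimate maximizes the averaged grid curve", {
  sim <- simulate_null(n_genes = 8, m = 300, q = 3, gamma_plus = 50, seed = 21)
  cfg <- dispersion_config("common", grid_length = 9,
                           grid_log10_range = c(0, 4))
  cm <- estimate_common(sim$data, sim$group, cfg)
  # exhaustive oracle: recompute every gene's APL on the grid directly
  grid <- 10^seq(0, 4, length.out = 9)
  avg <- sapply(grid, function(gp) mean(sapply(unclass(sim$data), function(g)
    as.numeric(adjusted_profile_loglik(g, sim$group, gp)))))
  expect_equal(as.numeric(cm), grid[which.max(avg)])
  # single gene: common equals the unmoderated genewise estimate
  one <- sim$data[1]
  cm1 <- estimate_common(one, sim$group, cfg)
  gw1 <- estimate_genewise(one, sim$group,
                           dispersion_config("genewise-none", grid_length = 9,
                                             grid_log10_range = c(0, 4)))
  expect_equal(as.numeric(cm1), gw1$gamma_plus)
  expect_error(estimate_common(dm_data(list()), sim$group, cfg), "empty")
})

test_that("moderation limits: W = 0 is unmoderated, huge W is common", {
  sim <- simulate_null(n_genes = 10, m = 300, q = 3, dispersion = "genewise",
                       seed = 22)
  cfg9 <- function(...) dispersion_config(grid_length = 9,
                                          grid_log10_range = c(0, 4), ...)
  none <- estimate_genewise(sim$data, sim$group, cfg9("genewise-none"))
  w0 <- estimate_genewise(sim$data, sim$group,
                          cfg9("genewise-moderate-common",
                               moderation_weight = 0))
  expect_equal(w0$gamma_plus, none$gamma_plus)
  wbig <- estimate_genewise(sim$data, sim$group,
                            cfg9("genewise-moderate-common",
                                 moderation_weight = 1e9))
  cm <- estimate_common(sim$data, sim$group, cfg9("common"))
  expect_true(all(wbig$gamma_plus == as.numeric(cm)))
})

test_that("all strategies agree on identical genes with W = 0", {
  g <- random_gene(q = 3, n = 6, seed = 13)
  genes <- lapply(1:6, function(i) gene_counts(paste0("g", i), g$counts))
  data <- dm_data(genes)
  grouping <- rep(c("A", "B"), each = 3)
  cfg <- function(mode) dispersion_config(mode, grid_length = 9,
                                          grid_log10_range = c(0, 4),
                                          moderation_weight = 0,
                                          trend_min_genes = 3)
  res <- lapply(c("genewise-none", "genewise-moderate-common",
                  "genewise-moderate-trend"), function(m)
    estimate_genewise(data, grouping, cfg(m))$gamma_plus)
  cmn <- estimate_common(data, grouping, cfg("common"))
  expect_true(all(vapply(res, identical, logical(1), res[[1]])))
  expect_equal(res[[1]][1], as.numeric(cmn))
})

test_that("trend neighborhoods follow the rank-window rule", {
  me <- stats::setNames(seq(100, 1, length.out = 100) + 0.1,
                        paste0("g", 1:100))
  cfg <- dispersion_config("genewise-moderate-trend",
                           trend_window_fraction = 0.1, trend_min_genes = 10)
  nb <- build_trend_sets(me, cfg)
  expect_true(all(lengths(nb) == 10))
  expect_true(all(vapply(seq_along(nb), function(g) g %in% nb[[g]],
                         logical(1))))
  # lowest-expression gene (here the last one) gets the bottom-ranked block
  expect_setequal(nb[[100]], 91:100)
  # brute-force oracle: sorted window around each gene's rank
  rk <- rank(me, ties.method = "first")
  ord <- order(me)
  for (g in c(1, 7, 50, 93, 100)) {
    lo <- min(max(rk[g] - 4, 1), 91)
    expect_setequal(nb[[g]], ord[lo:(lo + 9)])
  }
  expect_warning(build_trend_sets(me[1:5], cfg), "falling back")
})

test_that("common estimator recovers the truth and improves with sample size", {
  # parameter recovery at n = 10 vs 10
  sim <- simulate_null(n_genes = 150, n_per_group = 10, m = 1000, q = 3,
                       gamma_plus = 100, seed = 31)
  cm <- estimate_common(sim$data, sim$group, dispersion_config("common"))
  expect_lte(abs(log10(as.numeric(cm)) - 2), 0.2)
  # error shrinks (within grid resolution) as n grows
  err <- sapply(c(3, 5, 10), function(n) {
    s <- simulate_null(n_genes = 60, n_per_group = n, m = 1000, q = 3,
                       gamma_plus = 100, seed = 32)
    abs(log10(as.numeric(estimate_common(s$data, s$group,
                                         dispersion_config("common")))) - 2)
  })
  expect_true(err[3] <= err[1] + 0.301)
  expect_true(all(err <= 0.301))
})
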