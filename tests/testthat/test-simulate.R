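test_that("simulated counts respect the multinomial total and the seed", {
  sim <- simulate_null(n_genes = 6, m = 250, q = 3, gamma_plus = 40, seed = 81)
  for (g in names(sim$data))
    expect_true(all(column_totals(sim$data[[g]]) == 250))
  sim2 <- simulate_null(n_genes = 6, m = 250, q = 3, gamma_plus = 40,
                        seed = 81)
  expect_identical(lapply(unclass(sim$data), `[[`, "counts"),
                   lapply(unclass(sim2$data), `[[`, "counts"))
  # gene substreams: the first genes of a longer run are unchanged
  sim3 <- simulate_null(n_genes = 9, m = 250, q = 3, gamma_plus = 40,
                        seed = 81)
  expect_identical(sim$data[["g0001"]]$counts, sim3$data[["g0001"]]$counts)
})

test_that("the switch rule swaps the two most abundant features", {
  sim <- simulate_dtu(n_genes = 4, m = 300, q = 3,
                      proportions = c(0.6, 0.3, 0.1), gamma_plus = 50,
                      switch_fraction = 0.5, seed = 82)
  expect_equal(attr(sim$truth, "pi_alt"), c(0.3, 0.6, 0.1))
  expect_equal(sim$truth$ds, c(TRUE, TRUE, FALSE, FALSE))
  # switch_fraction 0 reproduces the null draw exactly
  a <- simulate_dtu(n_genes = 3, m = 100, q = 3, gamma_plus = 20,
                    switch_fraction = 0, seed = 83)
  b <- simulate_null(n_genes = 3, m = 100, q = 3, gamma_plus = 20, seed = 83)
  expect_identical(lapply(unclass(a$data), `[[`, "counts"),
                   lapply(unclass(b$data), `[[`, "counts"))
  # tied top-two proportions: the swap is a no-op, genes relabelled null
  tie <- simulate_dtu(n_genes = 2, m = 100, q = 3,
                      proportions = c(0.4, 0.4, 0.2), gamma_plus = 20,
                      switch_fraction = 1, seed = 84)
  expect_false(any(tie$truth$ds))
})

test_that("decaying proportions have the documented geometry", {
  expect_equal(decaying_proportions(2), c(2 / 3, 1 / 3))
  for (q in c(3, 5, 10)) {
    p <- decaying_proportions(q)
    expect_equal(sum(p), 1)
    expect_true(all(diff(p) < 0))
    expect_equal(p[1] / p[2], 2)
  }
  sim <- simulate_null(n_genes = 1, m = 60, q = 3, proportions = "uniform",
                       gamma_plus = 10, seed = 1)
  expect_equal(attr(sim$truth, "pi_null"), rep(1 / 3, 3))
})

test_that("generator moments match the DM moment formulas", {
  set.seed(85)
  m <- 200
  pi <- c(0.5, 0.3, 0.2)
  gp <- 25
  y <- rdirmnom(20000, m, pi, gp)
  mm <- dm_moments(m, pi, gp)
  se <- sqrt(diag(mm$covariance) / 20000)
  expect_true(all(abs(rowMeans(y) - mm$mean) <= 3 * se))
  # inflation factor via the summed variances
  den <- sum(m * pi * (1 - pi))
  u <- colSums(sweep(y, 1, rowMeans(y))^2) / den
  expect_lt(abs(mean(u) - mm$inflation_factor), 3 * sd(u) / sqrt(20000))
})

test_that("calibration summaries count calls correctly", {
  truth <- data.frame(gene_id = paste0("g", 1:10),
                      ds = rep(c(TRUE, FALSE), each = 5))
  res_all1 <- data.frame(gene_id = truth$gene_id, pvalue = 1, adj_pvalue = 1)
  ev <- evaluate_calibration(res_all1, truth)
  expect_equal(ev$fp_rate, 0)
  expect_equal(ev$power, 0)
  expect_true(all(ev$table$fdr == 0))
  # perfect separation
  res_sep <- data.frame(gene_id = truth$gene_id,
                        pvalue = rep(c(0, 1), each = 5),
                        adj_pvalue = rep(c(0, 1), each = 5))
  ev2 <- evaluate_calibration(res_sep, truth)
  expect_equal(ev2$power, 1)
  expect_true(all(ev2$table$fdr == 0))
  expect_equal(ev2$fp_rate, 0)
  # uniform null p-values land near the threshold
  set.seed(86)
  nn <- 20000
  res_u <- data.frame(gene_id = paste0("n", 1:nn), pvalue = runif(nn),
                      adj_pvalue = NA_real_)
  truth_u <- data.frame(gene_id = res_u$gene_id, ds = FALSE)
  ev3 <- evaluate_calibration(res_u, truth_u)
  expect_lt(abs(ev3$fp_rate - 0.05), 3 * sqrt(0.05 * 0.95 / nn))
  expect_error(evaluate_calibration(res_u[1:3, ],
                                    data.frame(gene_id = "zzz", ds = FALSE)),
               "misaligned")
})

test_that("estimator error summaries are medians of the right quantities", {
  truth <- data.frame(gene_id = paste0("g", 1:10), gamma_plus = rep(100, 10))
  exact <- data.frame(gene_id = truth$gene_id, gamma_plus = truth$gamma_plus)
  e0 <- estimator_error(exact, truth)
  expect_true(all(unlist(e0) == 0))
  offset <- data.frame(gene_id = truth$gene_id,
                       gamma_plus = truth$gamma_plus + 7)
  expect_equal(estimator_error(offset, truth)$median_raw_error, 7)
  # 10-gene fixture recomputed by hand
  set.seed(87)
  est <- data.frame(gene_id = truth$gene_id,
                    gamma_plus = truth$gamma_plus * 10^runif(10, -1, 1))
  e <- estimator_error(est, truth)
  expect_equal(e$median_abs_error_log10,
               median(abs(log10(est$gamma_plus) - 2)))
  expect_equal(e$median_raw_error,
               median(est$gamma_plus - 100))
})
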