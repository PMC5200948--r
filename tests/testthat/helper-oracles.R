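# Independent oracles used across tests; deliberately written as plain
# loops, sharing no code with the package internals.

# All count vectors of length q summing to m (columns of the result).
enumerate_counts <- function(m, q) {
  if (q == 1) return(matrix(m, 1, 1))
  cols <- list()
  for (k in 0:m) {
    sub <- enumerate_counts(m - k, q - 1)
    cols[[length(cols) + 1]] <- rbind(k, sub)
  }
  do.call(cbind, cols)
}

# Dispersion-parameterized DM pmf evaluated with the rising-factorial
# product form, term by term (no log-gamma).
dm_pmf_product_oracle <- function(y, pi, theta) {
  m <- sum(y)
  coef <- factorial(m) / prod(factorial(y))
  num <- 1
  for (j in seq_along(y)) {
    if (y[j] > 0) for (r in 1:y[j]) num <- num * (pi[j] * (1 - theta) + (r - 1) * theta)
  }
  den <- 1
  for (r in 1:m) den <- den * (1 - theta + (r - 1) * theta)
  coef * num / den
}

# Best log-likelihood over a barycentric grid of the 3-simplex (step 1/n).
simplex_grid_best <- function(counts, gamma_plus, n = 200) {
  best <- -Inf
  for (i in 1:(n - 2)) {
    for (j in 1:(n - 1 - i)) {
      p <- c(i, j, n - i - j) / n
      ll <- sum(lgamma(counts + gamma_plus * p) - lgamma(gamma_plus * p))
      if (ll > best) best <- ll
    }
  }
  best
}

# pi-dependent log-likelihood terms (shared by the grid oracle checks)
loglik_terms_oracle <- function(counts, pi, gamma_plus) {
  sum(lgamma(counts + gamma_plus * pi) - lgamma(gamma_plus * pi))
}

# small random gene for property checks
random_gene <- function(q = 3, n = 4, m = 300, gamma_plus = 50, seed = 1,
                        id = "g1") {
  set.seed(seed)
  pi <- as.numeric(rdirmnom(1, 100, rep(1 / q, q), 5)[, 1] + 1)
  pi <- pi / sum(pi)
  y <- rdirmnom(n, m, pi, gamma_plus)
  dimnames(y) <- list(paste0("f", 1:q), paste0("s", 1:n))
  gene_counts(id, y)
}
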