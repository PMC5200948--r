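# Likelihood internals. The per-gene DM log-likelihood splits into terms that
# depend on the proportions (through gamma = gamma_plus * pi) and per-sample
# constants in (m_i, gamma_plus). Fitting only ever needs the pi-dependent
# part; reported log-likelihoods include the constants.

# pi-dependent part: sum_ij lgamma(y_ij + gp*pi_j) - lgamma(gp*pi_j)
.dm_pi_terms <- function(counts, pi, gamma_plus) {
  g <- gamma_plus * pi
  sum(lgamma(counts + g) - lgamma(g))
}

# constants: per sample lchoose-multinomial + lgamma(gp) - lgamma(m_i + gp)
.dm_const_terms <- function(counts, gamma_plus) {
  m <- colSums(counts)
  sum(lgamma(m + 1)) - sum(lgamma(counts + 1)) +
    length(m) * lgamma(gamma_plus) - sum(lgamma(m + gamma_plus))
}

# Maximize the DM log-likelihood over the simplex at fixed gamma_plus for one
# block of samples (columns of `counts`). Optimization runs unconstrained in
# additive log-ratio (softmax) coordinates with the analytic gradient; this
# converges cleanly even when the maximizer sits on the simplex boundary
# (features unobserved in the block), where barrier-type constrained methods
# stall and bias the likelihood ratio. Reported proportions are floored at
# `floor` and renormalized.
.fit_group_pi <- function(counts, gamma_plus, floor = 1e-10,
                          reltol = 1e-12, maxit = 1000) {
  q <- nrow(counts)
  p0 <- rowSums(counts)
  p0 <- pmax(p0 / sum(p0), 1e-6)
  p0 <- p0 / sum(p0)
  if (q == 1L)
    return(list(pi = 1, loglik_terms = .dm_pi_terms(counts, 1, gamma_plus),
                converged = TRUE))
  fn <- function(z) {
    w <- c(z, 0); w <- w - max(w)
    p <- exp(w); p <- p / sum(p)
    -.dm_pi_terms(counts, p, gamma_plus)
  }
  gr <- function(z) {
    w <- c(z, 0); w <- w - max(w)
    p <- exp(w); p <- p / sum(p)
    gfull <- gamma_plus *
      rowSums(digamma(counts + gamma_plus * p) - digamma(gamma_plus * p))
    -(p * (gfull - sum(p * gfull)))[-q]
  }
  o <- stats::optim(log(p0[-q] / p0[q]), fn, gr, method = "BFGS",
                    control = list(reltol = reltol, maxit = maxit))
  w <- c(o$par, 0); w <- w - max(w)
  p <- exp(w); p <- p / sum(p)
  p <- pmax(p, floor); p <- p / sum(p)
  ll <- .dm_pi_terms(counts, p, gamma_plus)
  ll0 <- .dm_pi_terms(counts, p0, gamma_plus)
  if (ll < ll0) {  # never return worse than the initialization
    p <- p0
    ll <- ll0
  }
  list(pi = p, loglik_terms = ll, converged = o$convergence == 0L)
}

#' Joint log-likelihood of a gene under fixed DM parameters
#'
#' Sums [dm_log_pmf()] over all samples with positive total, each evaluated
#' at the proportion vector of its design group and the shared concentration.
#' Zero-total samples contribute a constant (probability one) and are
#' excluded.
#'
#' @param gene A [gene_counts()] object.
#' @param grouping Factor (or vector, optionally named by sample id)
#'   assigning samples to groups.
#' @param proportions q x c matrix of per-group proportion columns, with
#'   column names matching the group levels (a single vector is accepted for
#'   one group).
#' @param gamma_plus Positive concentration shared by all groups.
#' @return Scalar log-likelihood.
#' @export
gene_log_likelihood <- function(gene, grouping, proportions, gamma_plus) {
  stopifnot(inherits(gene, "gene_counts"))
  grouping <- .align_group(grouping, colnames(gene$counts))
  if (is.null(dim(proportions)))
    proportions <- matrix(proportions, ncol = 1,
                          dimnames = list(NULL, levels(grouping)[1]))
  missing <- setdiff(levels(droplevels(grouping)), colnames(proportions))
  if (length(missing) > 0)
    stop("no proportion vector for group(s): ", paste(missing, collapse = ", "))
  keep <- colSums(gene$counts) > 0
  ll <- 0
  for (k in levels(droplevels(grouping))) {
    sel <- keep & grouping == k
    if (!any(sel)) next
    y <- gene$counts[, sel, drop = FALSE]
    ll <- ll + .dm_pi_terms(y, proportions[, k], gamma_plus) +
      .dm_const_terms(y, gamma_plus)
  }
  ll
}

#' Maximum-likelihood feature proportions at fixed concentration
#'
#' For each design group, maximizes the DM log-likelihood over the proportion
#' simplex with the concentration held fixed. This is the inner nuisance
#' maximization used both by the profile-likelihood dispersion machinery and
#' by the likelihood-ratio test. The search is initialized at the group's
#' pooled observed proportions (floored and renormalized); the result never
#' has lower likelihood than that initialization.
#'
#' @inheritParams gene_log_likelihood
#' @param gamma_plus Fixed positive concentration.
#' @return A list with `proportions` (q x c matrix, one column per group),
#'   `converged` (logical per group), and `loglik` (the joint log-likelihood
#'   over all groups, constants included).
#' @export
estimate_proportions <- function(gene, grouping, gamma_plus) {
  stopifnot(inherits(gene, "gene_counts"))
  if (nrow(gene$counts) < 2L)
    stop("gene has fewer than 2 features; filter first")
  if (!is.numeric(gamma_plus) || length(gamma_plus) != 1L || gamma_plus <= 0)
    stop("'gamma_plus' must be a positive scalar")
  grouping <- .align_group(grouping, colnames(gene$counts))
  keep <- colSums(gene$counts) > 0
  lev <- levels(droplevels(grouping[keep]))
  if (length(lev) == 0)
    stop("no sample with positive total count")
  q <- nrow(gene$counts)
  pi_hat <- matrix(NA_real_, q, length(lev),
                   dimnames = list(rownames(gene$counts), lev))
  conv <- logical(length(lev))
  names(conv) <- lev
  ll <- 0
  for (k in lev) {
    sel <- keep & grouping == k
    y <- gene$counts[, sel, drop = FALSE]
    f <- .fit_group_pi(y, gamma_plus)
    pi_hat[, k] <- f$pi
    conv[k] <- f$converged
    ll <- ll + f$loglik_terms + .dm_const_terms(y, gamma_plus)
  }
  list(proportions = pi_hat, converged = conv, loglik = ll)
}
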