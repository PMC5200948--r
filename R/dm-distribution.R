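#' Dirichlet-multinomial log probability mass function
#'
#' Density of counts `y` under the Dirichlet-multinomial (DM) distribution
#' with mean proportions `pi` and concentration `gamma_plus`, i.e. Dirichlet
#' parameters `gamma = gamma_plus * pi`. The DM arises by drawing a
#' proportion vector from a Dirichlet distribution and then counts from a
#' multinomial; it models multivariate counts whose relative composition is
#' overdispersed relative to the multinomial. All computation is in log space
#' via `lgamma` so large totals are handled without overflow.
#'
#' @param y Integer vector of non-negative counts, one per feature.
#' @param pi Proportion vector on the simplex (positive, sums to 1).
#' @param gamma_plus Positive scalar concentration. Large values approach the
#'   multinomial; small values mean strong overdispersion.
#' @return The log probability, a finite scalar for valid inputs.
#' @examples
#' dm_log_pmf(c(3, 2, 1), c(0.5, 0.3, 0.2), gamma_plus = 10)
#' @seealso [dm_log_pmf_theta()] for the dispersion parameterization,
#'   [dm_moments()] for mean and covariance.
#' @export
dm_log_pmf <- function(y, pi, gamma_plus) {
  .check_counts(y)
  .check_simplex(pi)
  if (length(y) != length(pi))
    stop("'y' and 'pi' must have the same length")
  if (!is.numeric(gamma_plus) || length(gamma_plus) != 1L ||
      !is.finite(gamma_plus) || gamma_plus <= 0)
    stop("'gamma_plus' must be a positive finite scalar")
  m <- sum(y)
  g <- gamma_plus * pi
  lcoef <- lgamma(m + 1) - sum(lgamma(y + 1))
  if (gamma_plus > 1e6) {
    # rising-factorial form: Gamma(a + y) / Gamma(a) = prod_{r=0}^{y-1} (a + r).
    # Avoids the catastrophic cancellation of lgamma differences at huge
    # concentrations (the multinomial limit).
    num <- sum(unlist(lapply(seq_along(y), function(j)
      if (y[j] > 0) log(g[j] + 0:(y[j] - 1)) else numeric(0))))
    return(lcoef + num - sum(log(gamma_plus + 0:(m - 1))))
  }
  lcoef + lgamma(gamma_plus) - lgamma(m + gamma_plus) +
    sum(lgamma(y + g) - lgamma(g))
}

#' Dirichlet-multinomial log pmf in the dispersion parameterization
#'
#' The DM dispersion is `theta = 1 / (1 + gamma_plus)`, bounded in `[0, 1)`.
#' At `theta = 0` the distribution reduces exactly to the multinomial, which
#' is returned via [stats::dmultinom()]; for `theta > 0` the concentration
#' `gamma_plus = (1 - theta) / theta` is used.
#'
#' @inheritParams dm_log_pmf
#' @param theta Dispersion in `[0, 1)`.
#' @return Log probability scalar.
#' @export
dm_log_pmf_theta <- function(y, pi, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta >= 1)
    stop("'theta' must lie in [0, 1)")
  if (theta == 0) {
    .check_counts(y)
    .check_simplex(pi)
    return(stats::dmultinom(y, prob = pi, log = TRUE))
  }
  dm_log_pmf(y, pi, gamma_plus = (1 - theta) / theta)
}

#' Mean, covariance and overdispersion factor of DM counts
#'
#' For total count `m`, the DM mean is `m * pi` and the covariance is the
#' multinomial covariance `m * (diag(pi) - pi pi^T)` inflated by
#' `c = (m + gamma_plus) / (1 + gamma_plus)`, which tends to 1 as the
#' concentration grows (no overdispersion) and to `m` as it vanishes.
#'
#' @param m Positive integer total count.
#' @inheritParams dm_log_pmf
#' @return A list with components `mean` (length-q vector), `covariance`
#'   (q x q matrix) and `inflation_factor` (scalar `c`).
#' @export
dm_moments <- function(m, pi, gamma_plus) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  .check_simplex(pi)
  if (!is.numeric(gamma_plus) || length(gamma_plus) != 1L || gamma_plus <= 0)
    stop("'gamma_plus' must be a positive scalar")
  cc <- (m + gamma_plus) / (1 + gamma_plus)
  list(mean = m * pi,
       covariance = cc * m * (diag(pi, nrow = length(pi)) - tcrossprod(pi)),
       inflation_factor = cc)
}

#' Convert between Dirichlet parameter vectors and (proportions, concentration)
#'
#' A positive Dirichlet parameter vector `gamma` factors uniquely into mean
#' proportions `pi = gamma / sum(gamma)` and concentration
#' `gamma_plus = sum(gamma)`; the equivalent dispersion is
#' `theta = 1 / (1 + gamma_plus)`. `dm_parameterize()` performs the
#' decomposition and `dm_gamma_vector()` inverts it.
#'
#' @param gamma Strictly positive numeric vector of Dirichlet parameters.
#' @return `dm_parameterize()`: list with `proportions`, `gamma_plus`,
#'   `theta`. `dm_gamma_vector()`: the recomposed `gamma` vector.
#' @examples
#' p <- dm_parameterize(c(2, 2))   # proportions (0.5, 0.5), gamma_plus 4
#' dm_gamma_vector(p$proportions, p$gamma_plus)
#' @export
dm_parameterize <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) < 1L || any(!is.finite(gamma)) ||
      any(gamma <= 0))
    stop("'gamma' must be a strictly positive numeric vector")
  gp <- sum(gamma)
  list(proportions = gamma / gp, gamma_plus = gp, theta = 1 / (1 + gp))
}

#' @rdname dm_parameterize
#' @param proportions Simplex vector of mean proportions.
#' @param gamma_plus Positive concentration scalar.
#' @export
dm_gamma_vector <- function(proportions, gamma_plus) {
  .check_simplex(proportions)
  if (!is.numeric(gamma_plus) || length(gamma_plus) != 1L || gamma_plus <= 0)
    stop("'gamma_plus' must be a positive scalar")
  gamma_plus * proportions
}

#' Draw Dirichlet-multinomial count vectors
#'
#' For each of `n` draws a proportion vector is sampled from
#' Dirichlet(`gamma_plus * pi`) (via normalized gamma variates) and counts
#' from Multinomial(`m`, proportions).
#'
#' @param n Number of draws.
#' @param m Total count per draw (scalar, recycled).
#' @inheritParams dm_log_pmf
#' @return A `length(pi) x n` integer matrix, one draw per column.
#' @export
rdirmnom <- function(n, m, pi, gamma_plus) {
  .check_simplex(pi)
  if (gamma_plus <= 0) stop("'gamma_plus' must be positive")
  q <- length(pi)
  g <- gamma_plus * pi
  p <- matrix(stats::rgamma(n * q, shape = g), nrow = q)
  p <- sweep(p, 2, colSums(p), "/")
  out <- matrix(0L, nrow = q, ncol = n)
  for (i in seq_len(n)) out[, i] <- stats::rmultinom(1, m, p[, i])[, 1]
  out
}

# -- input checks ------------------------------------------------------------

.check_counts <- function(y) {
  if (!is.numeric(y) || length(y) < 1L || any(!is.finite(y)) ||
      any(y < 0) || any(y != round(y)))
    stop("counts must be finite non-negative integers")
  invisible(y)
}

.check_simplex <- function(pi, tol = 1e-8) {
  if (!is.numeric(pi) || length(pi) < 1L || any(!is.finite(pi)) ||
      any(pi <= 0) || any(pi > 1))
    stop("'pi' must have entries in (0, 1]")
  if (abs(sum(pi) - 1) > tol)
    stop("'pi' must sum to 1")
  invisible(pi)
}
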