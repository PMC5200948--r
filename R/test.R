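#' Full and null proportion fits for one gene
#'
#' The full model fits one proportion vector per design group; the null
#' model pools all samples into a single group. Both are maximized at the
#' same fixed concentration, so twice their log-likelihood difference is the
#' likelihood-ratio statistic for equal proportions.
#'
#' @inheritParams estimate_proportions
#' @return List with elements `full` and `null`, each as returned by
#'   [estimate_proportions()].
#' @export
fit_full_and_null <- function(gene, grouping, gamma_plus) {
  grouping <- .align_group(grouping, colnames(gene$counts))
  full <- estimate_proportions(gene, grouping, gamma_plus)
  null <- estimate_proportions(gene, rep("all", ncol(gene$counts)), gamma_plus)
  list(full = full, null = null)
}

#' Likelihood-ratio test of equal feature proportions
#'
#' Computes `D = 2 (l_full - l_null)` and refers it to a chi-squared
#' distribution with `(c - 1) * (q - 1)` degrees of freedom, where `c` is
#' the number of groups and `q` the number of features. Small negative `D`
#' from finite optimizer tolerance is clipped to zero; `D` below `-1e-6`
#' marks an optimizer failure and yields a missing p-value.
#'
#' @param gene A [gene_counts()] object.
#' @param full,null Fits from [fit_full_and_null()].
#' @param n_groups Number of design groups `c`.
#' @return One-row data frame: `gene_id`, `lr`, `df`, `pvalue`, `converged`.
#' @export
lrt <- function(gene, full, null, n_groups) {
  q <- nrow(gene$counts)
  df <- (n_groups - 1L) * (q - 1L)
  D <- 2 * (full$loglik - null$loglik)
  conv <- all(full$converged) && all(null$converged)
  if (D < -1e-6) {
    p <- NA_real_
    conv <- FALSE
  } else {
    D <- max(D, 0)
    p <- stats::pchisq(D, df = df, lower.tail = FALSE)
  }
  data.frame(gene_id = gene$gene_id, lr = max(D, 0), df = df, pvalue = p,
             converged = conv, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment with missing values preserved
#'
#' Step-up false-discovery-rate correction via [stats::p.adjust()]; missing
#' p-values are excluded from the ranking and reinserted as missing.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Test every fitted gene for differential usage
#'
#' Runs the likelihood-ratio test of equal proportions for each gene of a
#' [dm_fit()], at the gene's fitted concentration, and applies
#' Benjamini-Hochberg correction across genes.
#'
#' @param fit A `dm_fit` with at least two design groups.
#' @return A data frame of class `dm_test` with columns `gene_id`, `lr`,
#'   `df`, `pvalue`, `adj_pvalue`, `gamma_plus`, `converged`; the `skipped`
#'   attribute carries genes excluded before fitting.
#' @examples
#' sim <- simulate_null(n_genes = 5, n_per_group = 3, m = 200, q = 3,
#'                      gamma_plus = 50, seed = 1)
#' res <- dm_test(dm_fit(sim$data, sim$group, gamma_plus = 50))
#' res$pvalue
#' @export
dm_test <- function(fit) {
  stopifnot(inherits(fit, "dm_fit"))
  if (nlevels(droplevels(fit$group)) < 2L)
    stop("at least two design groups are required")
  c_groups <- nlevels(droplevels(fit$group))
  rows <- vector("list", length(fit$data))
  for (g in seq_along(fit$data)) {
    gene <- fit$data[[g]]
    gp <- fit$dispersion$gamma_plus[g]
    null <- estimate_proportions(gene, rep("all", ncol(gene$counts)), gp)
    row <- lrt(gene, fit$fits[[g]], null, c_groups)
    row$gamma_plus <- gp
    rows[[g]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(gene_id = character(0), lr = numeric(0),
                         df = integer(0), pvalue = numeric(0),
                         converged = logical(0), gamma_plus = numeric(0))
  out$adj_pvalue <- adjust_bh(out$pvalue)
  out <- out[, c("gene_id", "lr", "df", "pvalue", "adj_pvalue",
                 "gamma_plus", "converged")]
  structure(out, skipped = fit$skipped, class = c("dm_test", "data.frame"))
}

#' One-call differential transcript usage analysis
#'
#' Convenience wrapper: [dm_fit()] followed by [dm_test()]. The dataset is
#' expected to be pre-filtered (see [dm_filter()]).
#'
#' @inheritParams dm_fit
#' @return A `dm_test` results table.
#' @export
run_dtu <- function(data, group, config = dispersion_config(),
                    gamma_plus = NULL) {
  dm_test(dm_fit(data, group, config = config, gamma_plus = gamma_plus))
}

#' @export
print.dm_test <- function(x, ...) {
  cat("dm_test: ", nrow(x), " genes tested, ",
      sum(x$adj_pvalue <= 0.05, na.rm = TRUE),
      " at BH-adjusted p <= 0.05\n", sep = "")
  print.data.frame(utils::head(x[order(x$pvalue), ], 6))
  invisible(x)
}

#' P-value histogram of a results table
#' @param x A `dm_test`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.dm_test <- function(x, ...) {
  graphics::hist(x$pvalue, breaks = 20, freq = FALSE, xlab = "p-value",
                 main = "DTU p-values", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
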