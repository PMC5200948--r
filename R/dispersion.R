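#' Dispersion estimation settings
#'
#' Controls how the per-gene concentration `gamma_plus` is estimated. All
#' strategies evaluate the (Cox-Reid adjusted) profile log-likelihood on a
#' fixed grid of `grid_length` points equally spaced in log10 `gamma_plus`
#' over `grid_log10_range`; moderation then just adds weighted averages of
#' the cached per-gene curves, which keeps the empirical-Bayes step cheap and
#' numerically stable.
#'
#' @param mode One of `"genewise-moderate-common"` (default; each gene's
#'   curve is combined with the all-gene average curve), `"common"` (one
#'   shared estimate), `"genewise-none"` (no moderation), or
#'   `"genewise-moderate-trend"` (moderation towards genes of similar
#'   expression).
#' @param grid_length Number of grid points (>= 3).
#' @param grid_log10_range Range of log10 gamma_plus covered by the grid.
#' @param moderation_weight Non-negative weight `W`: the average curve counts
#'   as `W` pseudo-genes relative to the gene's own likelihood. `W = 0`
#'   reproduces unmoderated genewise estimation.
#' @param trend_window_fraction Fraction of genes forming each trend
#'   neighborhood (by rank of mean expression).
#' @param trend_min_genes Minimum neighborhood size; datasets smaller than
#'   this fall back to moderation towards the common curve.
#' @param adjustment `"cox-reid"` (default) penalizes the profile likelihood
#'   by half the log-determinant of the observed information of the nuisance
#'   proportions; `"none"` uses the raw profile likelihood.
#' @return A list of class `dispersion_config`.
#' @export
dispersion_config <- function(mode = c("genewise-moderate-common", "common",
                                       "genewise-none",
                                       "genewise-moderate-trend"),
                              grid_length = 21,
                              grid_log10_range = c(0, 6),
                              moderation_weight = 0.1,
                              trend_window_fraction = 0.1,
                              trend_min_genes = 50,
                              adjustment = c("cox-reid", "none")) {
  mode <- match.arg(mode)
  adjustment <- match.arg(adjustment)
  stopifnot(grid_length >= 3, length(grid_log10_range) == 2,
            grid_log10_range[1] < grid_log10_range[2],
            is.finite(moderation_weight), moderation_weight >= 0,
            trend_window_fraction > 0, trend_window_fraction <= 1,
            trend_min_genes >= 2)
  structure(list(mode = mode, grid_length = as.integer(grid_length),
                 grid_log10_range = grid_log10_range,
                 moderation_weight = moderation_weight,
                 trend_window_fraction = trend_window_fraction,
                 trend_min_genes = as.integer(trend_min_genes),
                 adjustment = adjustment),
            class = "dispersion_config")
}

#' Profile log-likelihood of the concentration
#'
#' The DM log-likelihood with the per-group proportions maximized out at the
#' given fixed `gamma_plus` (one proportion vector per design group).
#'
#' @inheritParams estimate_proportions
#' @return Scalar profile log-likelihood, with attributes `proportions` and
#'   `converged` from the inner fit.
#' @export
profile_loglik <- function(gene, grouping, gamma_plus) {
  fit <- estimate_proportions(gene, grouping, gamma_plus)
  structure(fit$loglik, proportions = fit$proportions,
            converged = fit$converged)
}

# Log-determinant of the observed information of the free proportion
# coordinates (q-1 per group, block diagonal across groups) at the fitted
# proportions. Analytic: for one group the Hessian of the log-likelihood is
# diag(d) + e * 11', with
#   d_a = gp^2 sum_i [psi1(y_ia + gp pi_a) - psi1(gp pi_a)],  a = 1..q-1,
#   e   = gp^2 sum_i [psi1(y_iq + gp pi_q) - psi1(gp pi_q)],
# so the information is diag(-d) - e * 11'. Returns NA when the information
# is not positive definite (degenerate data, e.g. a feature unobserved in a
# whole group).
.obs_info_logdet <- function(counts, pi, gamma_plus) {
  q <- nrow(counts)
  g <- gamma_plus * pi
  tri <- rowSums(trigamma(counts + g) - trigamma(g))
  d <- gamma_plus^2 * tri
  A <- diag(-d[-q], nrow = q - 1) + (-d[q]) * matrix(1, q - 1, q - 1)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  2 * sum(log(diag(R)))
}

#' Cox-Reid adjusted profile log-likelihood
#'
#' The profile log-likelihood penalized by half the log-determinant of the
#' observed information matrix of the nuisance proportions (q-1 free
#' coordinates per group, evaluated at their fitted values). The penalty
#' counters the bias of profiling out many nuisance parameters, which
#' otherwise overstates the concentration. When the information matrix is
#' not positive definite (degenerate data), the raw profile likelihood is
#' returned with attribute `fallback = TRUE`.
#'
#' @inheritParams estimate_proportions
#' @return Scalar APL with attributes `pl` (unadjusted value), `logdet`, and
#'   `fallback`.
#' @export
adjusted_profile_loglik <- function(gene, grouping, gamma_plus) {
  grouping <- .align_group(grouping, colnames(gene$counts))
  fit <- estimate_proportions(gene, grouping, gamma_plus)
  keep <- colSums(gene$counts) > 0
  logdet <- 0
  for (k in colnames(fit$proportions)) {
    sel <- keep & grouping == k
    ld <- .obs_info_logdet(gene$counts[, sel, drop = FALSE],
                           fit$proportions[, k], gamma_plus)
    if (is.na(ld)) {
      return(structure(fit$loglik, pl = fit$loglik, logdet = NA_real_,
                       fallback = TRUE))
    }
    logdet <- logdet + ld
  }
  structure(fit$loglik - logdet / 2, pl = fit$loglik, logdet = logdet,
            fallback = FALSE)
}

# Evaluate PL and APL for every gene on the concentration grid.
# Returns list(grid, pl, apl, fallback, mean_expression); pl/apl are
# G x L matrices of per-gene curves.
.apl_curves <- function(data, grouping, config) {
  grid <- 10^seq(config$grid_log10_range[1], config$grid_log10_range[2],
                 length.out = config$grid_length)
  G <- length(data)
  L <- length(grid)
  pl <- apl <- matrix(NA_real_, G, L,
                      dimnames = list(names(data), signif(grid, 6)))
  fallback <- matrix(FALSE, G, L)
  me <- numeric(G)
  for (g in seq_len(G)) {
    gene <- data[[g]]
    me[g] <- mean(colSums(gene$counts))
    for (l in seq_len(L)) {
      a <- adjusted_profile_loglik(gene, grouping, grid[l])
      apl[g, l] <- as.numeric(a)
      pl[g, l] <- attr(a, "pl")
      fallback[g, l] <- attr(a, "fallback")
    }
  }
  list(grid = grid, pl = pl, apl = apl, fallback = fallback,
       mean_expression = stats::setNames(me, names(data)))
}

# argmax over the grid with ties broken towards the smaller gamma_plus
# (more dispersion, conservative).
.grid_argmax <- function(v) {
  which(v >= max(v) - 0)[1]
}

#' Common concentration estimate
#'
#' Maximizes the across-gene average adjusted profile log-likelihood over the
#' grid, assuming one shared concentration for all genes. Grid ties are
#' broken towards the smaller value (the conservative direction).
#'
#' @param data A [dm_data()] dataset (already filtered).
#' @inheritParams estimate_proportions
#' @param config A [dispersion_config()].
#' @param curves Optional precomputed curves (internal reuse).
#' @return Scalar `gamma_plus` with attributes `at_boundary` and `curve`
#'   (the averaged grid curve).
#' @export
estimate_common <- function(data, grouping, config = dispersion_config(),
                            curves = NULL) {
  stopifnot(inherits(data, "dm_data"))
  if (length(data) == 0) stop("empty dataset")
  if (is.null(curves)) curves <- .apl_curves(data, grouping, config)
  obj <- if (config$adjustment == "cox-reid") curves$apl else curves$pl
  avg <- colMeans(obj)
  i <- .grid_argmax(avg)
  structure(curves$grid[i],
            at_boundary = i == 1L || i == length(curves$grid),
            curve = avg)
}

#' Trend neighborhoods by mean expression
#'
#' Ranks genes by mean expression and assigns each gene the window of
#' `ceiling(fraction * G)` genes (at least `trend_min_genes`) centered on its
#' rank, truncated at the extremes so every window has full size. Used for
#' moderation towards an expression-dependent trend.
#'
#' @param mean_expressions Named numeric vector of per-gene mean expression
#'   (arithmetic mean over samples of the per-sample gene totals).
#' @param config A [dispersion_config()].
#' @return List of integer index vectors (into the input order), one per
#'   gene; each contains the gene itself. `NULL` with a warning when fewer
#'   genes than the minimum window size are supplied.
#' @export
build_trend_sets <- function(mean_expressions, config = dispersion_config()) {
  G <- length(mean_expressions)
  w <- max(ceiling(config$trend_window_fraction * G), config$trend_min_genes)
  if (G < w) {
    warning("fewer genes (", G, ") than the minimum trend window (", w,
            "); falling back to moderation towards the common curve")
    return(NULL)
  }
  rk <- rank(mean_expressions, ties.method = "first")
  ord <- order(rk)  # gene indices sorted by expression
  lapply(seq_len(G), function(g) {
    lo <- min(max(rk[g] - (w - 1L) %/% 2L, 1L), G - w + 1L)
    ord[lo:(lo + w - 1L)]
  })
}

#' Genewise concentration estimates with optional moderation
#'
#' Per gene, maximizes `APL_g + W * avg` over the grid, where `avg` is the
#' mean curve of all genes (moderation to common), of the gene's trend
#' neighborhood (moderation to trend), or absent (`W = 0` or mode
#' `genewise-none`). Estimates at the first or last grid point are flagged
#' `at_boundary`.
#'
#' @inheritParams estimate_common
#' @param trend_sets Neighborhoods from [build_trend_sets()]; computed
#'   automatically when the mode requires them.
#' @return A data frame of class `dm_dispersion` with columns `gene_id`,
#'   `gamma_plus`, `at_boundary`, `mean_expression`, plus attributes `grid`
#'   and `curves`.
#' @export
estimate_genewise <- function(data, grouping, config = dispersion_config(),
                              curves = NULL, trend_sets = NULL) {
  stopifnot(inherits(data, "dm_data"))
  if (length(data) == 0) stop("empty dataset")
  if (is.null(curves)) curves <- .apl_curves(data, grouping, config)
  obj <- if (config$adjustment == "cox-reid") curves$apl else curves$pl
  G <- nrow(obj)
  W <- config$moderation_weight
  mode <- config$mode
  if (mode == "genewise-moderate-trend" && is.null(trend_sets)) {
    trend_sets <- build_trend_sets(curves$mean_expression, config)
    if (is.null(trend_sets)) mode <- "genewise-moderate-common"
  }
  target <- switch(mode,
    "genewise-none" = NULL,
    "common" = NULL,
    "genewise-moderate-common" = matrix(colMeans(obj), G, ncol(obj),
                                        byrow = TRUE),
    "genewise-moderate-trend" = t(vapply(trend_sets, function(idx)
      colMeans(obj[idx, , drop = FALSE]), numeric(ncol(obj)))))
  est <- numeric(G)
  boundary <- logical(G)
  if (mode == "common") {
    cm <- estimate_common(data, grouping, config, curves = curves)
    est[] <- as.numeric(cm)
    boundary[] <- attr(cm, "at_boundary")
  } else {
    for (g in seq_len(G)) {
      v <- obj[g, ]
      if (!is.null(target) && W > 0) v <- v + W * target[g, ]
      i <- .grid_argmax(v)
      est[g] <- curves$grid[i]
      boundary[g] <- i == 1L || i == length(curves$grid)
    }
  }
  out <- data.frame(gene_id = names(data), gamma_plus = est,
                    at_boundary = boundary,
                    mean_expression = unname(curves$mean_expression),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, grid = curves$grid, curves = curves, mode = mode,
            class = c("dm_dispersion", "data.frame"))
}

#' Estimate per-gene concentrations
#'
#' Front end tying grid evaluation, the common estimate, and the moderated
#' genewise strategies together according to the configuration.
#'
#' @inheritParams estimate_common
#' @return A `dm_dispersion` data frame (see [estimate_genewise()]).
#' @export
dm_dispersion <- function(data, grouping, config = dispersion_config()) {
  estimate_genewise(data, grouping, config)
}

#' @export
print.dm_dispersion <- function(x, ...) {
  cat("dm_dispersion (", attr(x, "mode"), "): ", nrow(x), " genes; ",
      sum(x$at_boundary), " at grid boundary\n", sep = "")
  print.data.frame(utils::head(x, 6))
  invisible(x)
}
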