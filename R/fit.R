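#' Fit Dirichlet-multinomial usage models across genes
#'
#' For every gene, estimates (or accepts) a concentration `gamma_plus` and
#' fits the per-group feature proportions by maximum likelihood at that
#' concentration. The returned object is the full-model fit used by
#' [dm_test()] for the likelihood-ratio test of equal proportions.
#'
#' Genes that cannot be fitted (fewer than two features, or a design group
#' with no positive-count sample) are skipped with a recorded reason rather
#' than dropped silently.
#'
#' @param data A [dm_data()] dataset, normally already filtered with
#'   [dm_filter()].
#' @param group Factor (or vector, optionally named by sample id) of design
#'   groups, one per sample.
#' @param config A [dispersion_config()] controlling concentration
#'   estimation. Ignored when `gamma_plus` is supplied.
#' @param gamma_plus Optional known concentration: a scalar applied to all
#'   genes, or a vector named by gene id. When given, no dispersion
#'   estimation is performed (useful for simulations with known truth).
#' @return An object of class `dm_fit` with components `data`, `group`,
#'   `dispersion` (per-gene table), `fits` (per-gene proportion fits),
#'   `skipped` (data frame of gene_id, reason), and `config`.
#' @examples
#' sim <- simulate_null(n_genes = 5, n_per_group = 3, m = 200, q = 3,
#'                      gamma_plus = 50, seed = 1)
#' fit <- dm_fit(sim$data, sim$group, gamma_plus = 50)
#' coef(fit)[[1]]
#' @export
dm_fit <- function(data, group, config = dispersion_config(),
                   gamma_plus = NULL) {
  stopifnot(inherits(data, "dm_data"))
  group <- if (length(data) == 0) factor(unname(group))
           else .align_group(group, dm_samples(data))
  # canonical sample order: results must not depend on input column order
  ord <- order(dm_samples(data))
  if (length(data) > 0 && !identical(ord, seq_along(ord))) {
    ids <- dm_samples(data)[ord]
    names(group) <- dm_samples(data)
    data <- .reorder_samples(data, ids)
    group <- .align_group(group, ids)
  }
  skipped <- data.frame(gene_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  usable <- logical(length(data))
  for (g in seq_along(data)) {
    gene <- data[[g]]
    if (nrow(gene$counts) < 2L) {
      skipped <- rbind(skipped, data.frame(gene_id = gene$gene_id,
                                           reason = "fewer than 2 features"))
      next
    }
    pos <- colSums(gene$counts) > 0
    if (any(tapply(pos, group, sum) == 0)) {
      skipped <- rbind(skipped,
                       data.frame(gene_id = gene$gene_id,
                                  reason = "group without positive-count sample"))
      next
    }
    usable[g] <- TRUE
  }
  data_use <- data[usable]
  disp <- NULL
  if (length(data_use) > 0) {
    if (!is.null(gamma_plus)) {
      gp <- if (length(gamma_plus) == 1L)
        stats::setNames(rep(as.numeric(gamma_plus), length(data_use)),
                        names(data_use))
      else {
        if (is.null(names(gamma_plus)) ||
            !all(names(data_use) %in% names(gamma_plus)))
          stop("per-gene 'gamma_plus' must be named by gene id")
        gamma_plus[names(data_use)]
      }
      if (any(gp <= 0)) stop("'gamma_plus' must be positive")
      disp <- data.frame(gene_id = names(data_use), gamma_plus = unname(gp),
                         at_boundary = FALSE,
                         mean_expression = vapply(unclass(data_use), function(x)
                           mean(colSums(x$counts)), numeric(1)),
                         row.names = NULL, stringsAsFactors = FALSE)
      attr(disp, "mode") <- "fixed"
      class(disp) <- c("dm_dispersion", "data.frame")
    } else {
      disp <- dm_dispersion(data_use, group, config)
    }
  }
  fits <- vector("list", length(data_use))
  names(fits) <- names(data_use)
  for (g in seq_along(data_use)) {
    fits[[g]] <- estimate_proportions(data_use[[g]], group,
                                      disp$gamma_plus[g])
  }
  structure(list(data = data_use, group = group, dispersion = disp,
                 fits = fits, skipped = skipped, config = config),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat("dm_fit: ", length(x$data), " genes fitted (",
      nrow(x$skipped), " skipped), ",
      nlevels(x$group), " groups [", paste(levels(x$group), collapse = ", "),
      "]\n", sep = "")
  if (!is.null(x$dispersion))
    cat("concentration (", attr(x$dispersion, "mode"), "): median ",
        signif(stats::median(x$dispersion$gamma_plus), 4), ", ",
        sum(x$dispersion$at_boundary), " at grid boundary\n", sep = "")
  invisible(x)
}

#' @export
summary.dm_fit <- function(object, ...) {
  conv <- vapply(object$fits, function(f) all(f$converged), logical(1))
  out <- list(n_genes = length(object$data),
              n_skipped = nrow(object$skipped),
              groups = table(object$group),
              gamma_plus = if (is.null(object$dispersion)) NULL
                           else summary(object$dispersion$gamma_plus),
              n_boundary = if (is.null(object$dispersion)) 0L
                           else sum(object$dispersion$at_boundary),
              n_nonconverged = sum(!conv))
  class(out) <- "summary.dm_fit"
  out
}

#' @export
print.summary.dm_fit <- function(x, ...) {
  cat("Genes fitted:", x$n_genes, " skipped:", x$n_skipped, "\n")
  cat("Samples per group:\n"); print(x$groups)
  if (!is.null(x$gamma_plus)) {
    cat("Concentration estimates:\n"); print(x$gamma_plus)
    cat("At grid boundary:", x$n_boundary, "\n")
  }
  cat("Genes with non-converged proportion fits:", x$n_nonconverged, "\n")
  invisible(x)
}

#' Fitted per-group proportions
#'
#' @param object A `dm_fit`.
#' @param ... Unused.
#' @return Named list of q x c proportion matrices, one per gene.
#' @export
coef.dm_fit <- function(object, ...) {
  lapply(object$fits, `[[`, "proportions")
}

#' Expected per-sample feature counts under the fitted model
#'
#' The DM mean for sample i is `m_i * pi_hat` of the sample's group, with
#' the observed totals treated as fixed.
#'
#' @param object A `dm_fit`.
#' @param ... Unused.
#' @return Named list of q x n matrices of fitted means.
#' @export
predict.dm_fit <- function(object, ...) {
  grp <- as.character(object$group)
  lapply(seq_along(object$data), function(g) {
    gene <- object$data[[g]]
    pi_hat <- object$fits[[g]]$proportions
    m <- colSums(gene$counts)
    out <- pi_hat[, grp, drop = FALSE] %*% diag(m, length(m))
    dimnames(out) <- dimnames(gene$counts)
    out
  }) |> stats::setNames(names(object$data))
}

#' Pearson residuals of the fitted DM model
#'
#' Observed minus fitted counts, scaled by the DM standard deviation
#' `sqrt(c_i * m_i * pi (1 - pi))` with inflation factor
#' `c_i = (m_i + gamma_plus) / (1 + gamma_plus)`.
#'
#' @param object A `dm_fit`.
#' @param ... Unused.
#' @return Named list of q x n residual matrices.
#' @export
residuals.dm_fit <- function(object, ...) {
  grp <- as.character(object$group)
  out <- lapply(seq_along(object$data), function(g) {
    gene <- object$data[[g]]
    pi_hat <- object$fits[[g]]$proportions[, grp, drop = FALSE]
    m <- colSums(gene$counts)
    gp <- object$dispersion$gamma_plus[g]
    mu <- sweep(pi_hat, 2, m, "*")
    cc <- (m + gp) / (1 + gp)
    v <- sweep(pi_hat * (1 - pi_hat), 2, cc * m, "*")
    r <- (gene$counts - mu) / sqrt(v)
    r[v == 0] <- 0
    dimnames(r) <- dimnames(gene$counts)
    r
  })
  stats::setNames(out, names(object$data))
}

#' Concentration versus expression diagnostic plot
#'
#' Scatter of the per-gene concentration estimates against mean expression
#' on log-log axes, with boundary estimates highlighted.
#'
#' @param x A `dm_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dm_fit <- function(x, ...) {
  d <- x$dispersion
  graphics::plot(d$mean_expression, d$gamma_plus, log = "xy",
                 xlab = "mean expression (counts)",
                 ylab = expression(hat(gamma)["+"]),
                 pch = ifelse(d$at_boundary, 4, 16),
                 col = ifelse(d$at_boundary, "red", "grey30"), ...)
  invisible(x)
}

#' Parametric simulation from a fitted model
#'
#' Draws new datasets from the fitted DM parameters: for each gene and
#' sample, proportions from Dirichlet(`gamma_hat * pi_hat(group)`) and
#' counts from a multinomial with the observed sample total.
#'
#' @param object A `dm_fit`.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` [dm_data()] datasets.
#' @export
simulate.dm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grp <- as.character(object$group)
  replicate(nsim, simplify = FALSE, {
    genes <- lapply(seq_along(object$data), function(g) {
      gene <- object$data[[g]]
      pi_hat <- object$fits[[g]]$proportions
      gp <- object$dispersion$gamma_plus[g]
      m <- colSums(gene$counts)
      y <- matrix(0, nrow(gene$counts), ncol(gene$counts),
                  dimnames = dimnames(gene$counts))
      for (i in seq_along(m))
        y[, i] <- rdirmnom(1, m[i], pi_hat[, grp[i]], gp)[, 1]
      gene_counts(gene$gene_id, y)
    })
    dm_data(genes)
  })
}
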