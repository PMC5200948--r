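#' Expression filter thresholds
#'
#' Thresholds for feature- and gene-level expression filtering before model
#' fitting. The `"tuqtl"` mode carries the large-cohort defaults (a feature
#' must reach 10 counts and 5% within-sample usage in at least 5 samples;
#' a gene must reach 10 counts in at least 70 samples); `"dtu"` relaxes the
#' sample-count rules to suit small two-group designs.
#'
#' @param mode `"dtu"` or `"tuqtl"`; selects the default sample thresholds.
#' @param min_feature_count Minimum count a feature must reach in a sample.
#' @param min_feature_prop Minimum within-sample usage proportion (jointly
#'   with the count rule, in the same sample).
#' @param min_samps_feature Number of samples in which a feature must meet
#'   both rules.
#' @param min_gene_count Minimum per-sample gene total.
#' @param min_samps_gene Number of samples in which the gene total rule must
#'   hold.
#' @param min_features_per_gene Minimum surviving features (>= 2; a gene
#'   with one feature has no usage to model).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(mode = c("dtu", "tuqtl"),
                          min_feature_count = 10,
                          min_feature_prop = 0.05,
                          min_samps_feature = if (mode == "tuqtl") 5 else 3,
                          min_gene_count = 10,
                          min_samps_gene = if (mode == "tuqtl") 70 else 3,
                          min_features_per_gene = 2) {
  mode <- match.arg(mode)
  stopifnot(min_feature_count >= 0, min_feature_prop >= 0,
            min_samps_feature >= 0, min_gene_count >= 0,
            min_samps_gene >= 0, min_features_per_gene >= 2)
  structure(list(mode = mode,
                 min_feature_count = min_feature_count,
                 min_feature_prop = min_feature_prop,
                 min_samps_feature = min_samps_feature,
                 min_gene_count = min_gene_count,
                 min_samps_gene = min_samps_gene,
                 min_features_per_gene = min_features_per_gene),
            class = "filter_config")
}

#' Filter lowly used features of one gene
#'
#' Keeps features that, in at least `min_samps_feature` samples, have both a
#' count of at least `min_feature_count` and a within-sample usage
#' proportion of at least `min_feature_prop`. Proportions are computed
#' against the gene total *before* any feature is removed (the rule
#' describes observed relative usage in the raw data); zero-total samples
#' contribute to no feature's tally.
#'
#' @param gene A [gene_counts()] object.
#' @param config A [filter_config()].
#' @return A `gene_counts` with the surviving features (possibly fewer than
#'   two; [filter_genes()] removes such genes).
#' @export
filter_features <- function(gene, config = filter_config()) {
  stopifnot(inherits(gene, "gene_counts"))
  m <- colSums(gene$counts)
  pos <- m > 0
  if (!any(pos)) {
    keep <- rep(FALSE, nrow(gene$counts))
  } else {
    prop <- sweep(gene$counts[, pos, drop = FALSE], 2, m[pos], "/")
    ok <- gene$counts[, pos, drop = FALSE] >= config$min_feature_count &
      prop >= config$min_feature_prop
    keep <- rowSums(ok) >= config$min_samps_feature
  }
  gene_counts(gene$gene_id, gene$counts[keep, , drop = FALSE])
}

#' Filter genes by total expression and surviving features
#'
#' Applied after [filter_features()]: a gene is kept when its total count
#' reaches `min_gene_count` in at least `min_samps_gene` samples and at
#' least `min_features_per_gene` features survived.
#'
#' @param data A [dm_data()] dataset (feature-filtered).
#' @param config A [filter_config()].
#' @return Filtered `dm_data`; attribute `filter_summary` records per-gene
#'   feature counts before/after and the kept flag.
#' @export
filter_genes <- function(data, config = filter_config()) {
  stopifnot(inherits(data, "dm_data"))
  kept <- vapply(unclass(data), function(g) {
    m <- colSums(g$counts)
    sum(m >= config$min_gene_count) >= config$min_samps_gene &&
      nrow(g$counts) >= config$min_features_per_gene
  }, logical(1))
  out <- data[kept]
  attr(out, "filter_summary") <- data.frame(
    gene_id = names(data),
    n_features = vapply(unclass(data), function(g) nrow(g$counts), 1L),
    kept = unname(kept), row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Feature- and gene-level expression filtering
#'
#' Runs [filter_features()] on every gene, then [filter_genes()]. Filtering
#' is idempotent... applying the same configuration twice changes nothing,
#' because decisions use the raw (pre-removal) gene totals of the data they
#' are given.
#'
#' @inheritParams filter_genes
#' @return Filtered `dm_data` with a `filter_summary` attribute listing
#'   features before/after and the kept flag per gene.
#' @export
dm_filter <- function(data, config = filter_config()) {
  stopifnot(inherits(data, "dm_data"))
  before <- vapply(unclass(data), function(g) nrow(g$counts), 1L)
  feat <- dm_data(lapply(unclass(data), filter_features, config = config))
  out <- filter_genes(feat, config)
  fs <- attr(out, "filter_summary")
  fs$n_features_before <- unname(before)
  names(fs)[names(fs) == "n_features"] <- "n_features_after"
  attr(out, "filter_summary") <-
    fs[, c("gene_id", "n_features_before", "n_features_after", "kept")]
  out
}

#' Drop features never reaching a usage fraction
#'
#' The differential-splicing pre-filter: removes features whose within-sample
#' usage proportion is below `threshold` in *every* sample with positive
#' gene total. Distinct from [filter_features()], which requires joint
#' count-and-proportion support in a minimum number of samples.
#'
#' @param data A [dm_data()] dataset.
#' @param threshold Usage fraction below which a feature must stay in all
#'   samples to be removed (default 0.05; 0 disables the filter).
#' @return Filtered `dm_data`.
#' @export
prefilter_low_fraction <- function(data, threshold = 0.05) {
  stopifnot(inherits(data, "dm_data"), threshold >= 0)
  dm_data(lapply(unclass(data), function(g) {
    m <- colSums(g$counts)
    pos <- m > 0
    if (!any(pos)) {
      keep <- rep(FALSE, nrow(g$counts))
    } else {
      prop <- sweep(g$counts[, pos, drop = FALSE], 2, m[pos], "/")
      keep <- apply(prop >= threshold, 1, any)
    }
    if (threshold == 0) keep <- rep(TRUE, nrow(g$counts))
    gene_counts(g$gene_id, g$counts[keep, , drop = FALSE])
  }))
}
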