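---
title: "Modelling differential transcript usage with the Dirichlet-multinomial"
author: "dmusage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling differential transcript usage with the Dirichlet-multinomial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmusage)
```

## The model

A gene with $q$ countable features (transcripts, exonic bins, junctions)
yields, in sample $i$, a count vector $y_i = (y_{1i}, \dots, y_{qi})$ with
total $m_i = \sum_j y_{ji}$. The total reflects sequencing depth and overall
gene expression, not the quantity of interest — the *relative usage* of the
features — so `dmusage` conditions on it throughout and treats $m_i$ as
ancillary. No library-size normalization is applied anywhere: conditioning
on the totals makes it unnecessary.

Under the multinomial model the usage proportions $\pi$ would be identical
in every sample of a condition. Biological replicates and quantification
noise overdisperse real data, so the proportions themselves are modelled as
random: $\Pi \sim \mathrm{Dirichlet}(\gamma_+ \pi)$, giving the
Dirichlet-multinomial (DM) marginal for the counts. The concentration
$\gamma_+ > 0$ controls overdispersion: the covariance of the counts is the
multinomial covariance inflated by $c = (m + \gamma_+)/(1 + \gamma_+)$, so
$\gamma_+ \to \infty$ recovers the multinomial and small $\gamma_+$ means
strongly variable usage. The equivalent dispersion is
$\theta = 1/(1+\gamma_+) \in [0, 1)$; `dm_log_pmf_theta()` exposes this
parameterization and reduces exactly to the multinomial at $\theta = 0$.
All densities are computed in log space through `lgamma`; for extreme
concentrations (beyond $10^6$) the rising-factorial form of the density is
used instead, because differences of `lgamma` at arguments of order
$10^{12}$ lose more absolute precision than the multinomial limit tolerates.

## Testing for differential usage

For a comparison across $c$ conditions the null hypothesis is equality of
the proportion vectors, $H_0: \pi_1 = \dots = \pi_c$, with the concentration
treated as a per-gene nuisance estimated in a first step and then held
fixed. The statistic is the likelihood ratio
$D = 2\,\{\ell(\hat\pi_1, \dots, \hat\pi_c; \hat\gamma_+) -
\ell(\hat\pi; \hat\gamma_+)\}$, referred to $\chi^2$ with $(c-1)(q-1)$
degrees of freedom; Benjamini-Hochberg correction is applied across genes.
Genes whose optimization fails are reported with missing p-values rather
than dropped, and $D$ below $-10^{-6}$ (an optimizer failure, never
observed in the test suite) marks the gene unconverged.

The inner maximization over the proportion simplex at fixed $\gamma_+$ is
performed by BFGS in additive log-ratio (softmax) coordinates with the
analytic gradient, initialized at the pooled observed proportions (floored
at $10^{-6}$ and renormalized); reported proportions are floored at
$10^{-10}$. This parameterization was chosen deliberately over a
box-constrained search on the $q-1$ free coordinates: when a feature is
unobserved in a group the maximizer sits on the simplex boundary, and
barrier-type constrained optimizers stall before reaching it. The
shortfall is not cosmetic — an under-maximized full model biases the
likelihood-ratio statistic downward (we measured a mean statistic of 8.0
against 9 expected for $q = 10$ decaying proportions), inverting the
test's documented finite-sample behaviour. With the softmax
parameterization the same design gives a mean statistic of 9.6 and the
expected *inflation* of the false positive rate (about 0.07 at the 0.05
level), while few uniform features stay calibrated. The fitted value is
never allowed to fall below its initialization.

This inflation for many features with decaying proportions — even when the
*true* concentration is supplied — is a property of the chi-squared
approximation with tiny expected counts in the rare categories, and the
package's acceptance suite asserts it rather than hiding it.

## Concentration estimation

Plain maximum likelihood underestimates variance parameters because the
nuisance proportions are estimated from the same data. `dmusage` therefore
maximizes the *profile* log-likelihood $PL(\gamma_+)$ (proportions
maximized out per design group) with the Cox-Reid correction:
$APL(\gamma_+) = PL(\gamma_+) - \tfrac12 \log \det I$, where $I$ is the
observed information of the $q-1$ free proportion coordinates per group
(block diagonal across groups), computed analytically from trigamma terms.
The information already scales with the data, so no further factor of $m$
is applied. When $I$ is singular — typically a feature with no counts in
an entire group — the raw profile likelihood is used for that gene and
grid point, and the event is flagged.

Estimation is by grid search: 21 points equally spaced in
$\log_{10}\gamma_+$ over $[0, 6]$ by default. The per-gene $APL$ curves
are cached, which makes every moderation strategy a cheap weighted sum of
curves and avoids any instability of continuous optimization on flat
likelihoods. Ties on the grid break towards the smaller concentration —
more dispersion, hence fewer false positives. Estimates at either end of
the grid are flagged `at_boundary`.

Four strategies share the curves:

* **common** — one value maximizing the across-gene average curve;
* **genewise-none** — each gene's own maximum;
* **genewise-moderate-common** (default) — maximize
  $APL_g + W \cdot \overline{APL}$, the empirical-Bayes compromise;
* **genewise-moderate-trend** — the average is taken over the gene's trend
  neighborhood: genes are ranked by mean expression (arithmetic mean of
  per-sample totals, unnormalized) and each gene gets the window of
  $\lceil 0.1\,G \rceil$ (at least 50) genes centered on its rank,
  truncated at the extremes.

The moderation weight $W$ counts the averaged curve as $W$ pseudo-genes
against the gene's own likelihood. Its default, $W = 0.1$, was calibrated
on this package's own simulations rather than copied from anywhere: with
per-gene true concentrations spread over two decades
($\log_{10}\gamma_+ \sim U[1,3]$, 3 vs 3 samples), weights of 0.5 and
above drag every estimate towards the centre strongly enough to *worsen*
the median $\log_{10}$ error relative to unmoderated estimation, while
$W = 0.1$ both improves the median error and eliminates the
boundary-of-grid estimates that plague unmoderated genewise fitting. Users
with many replicates can lower it further; `W = 0` is exactly unmoderated
estimation.

## Transcript-usage QTLs

In the QTL mode the grouping is the minor-allele dosage (0/1/2, treated as
unordered categories) of SNPs near each gene. SNPs are retained when they
lie within the gene body extended by 5 kb on each side (1-based inclusive
coordinates, window clipped at position 1), show at least two distinct
observed dosages, and have carriers (dosage 1 or 2) in at least 5 samples.
Missing genotypes are excluded per test, never imputed. SNPs with
identical genotype vectors — including the missingness pattern — define
identical models, so they are collapsed into blocks and each block is
tested once; per-SNP results are recoverable exactly from their block.

The gene-level concentration is estimated once from the whole cohort with
no grouping and reused for every block of the gene; re-estimating per
block would cost quadratically and contradicts the two-step treatment of
the nuisance.

Because many correlated SNPs are tested per gene, nominal p-values are
adjusted by permutation: the count columns are permuted (genotypes fixed),
all blocks re-tested, and the per-gene minimum p recorded; the adjusted
p-value is $(1 + \#\{\min_b p^{perm} \le \min_b p^{obs}\})/(1 + B)$ with
$B = 100$ permutations by default. BH correction across genes is applied
to the adjusted values, and per-block empirical p-values against the
pooled permutation null are reported as well. The permutation scheme is
the min-p scheme standard in the splicing-QTL literature; it is a
documented approximation, and the +1 smoothing makes the smallest
attainable adjusted p equal to $1/(B+1)$. Samples are analyzed in sorted
id order and SNPs in position order, so results are invariant to input
ordering; permutations derive from per-gene substreams of the seed.

## Filtering

Two distinct filters are provided. `dm_filter()` implements joint
count-and-usage support: a feature survives when it has at least 10 counts
*and* at least 5% within-sample usage in the same sample, in at least 5
samples (large-cohort `"tuqtl"` defaults; the `"dtu"` mode relaxes the
sample thresholds to 3 for small designs); a gene survives with at least
10 total counts in enough samples (70 for cohorts, 3 for small designs)
and at least two surviving features. Usage denominators are the gene
totals *before* feature removal — the rule describes observed relative
usage in the raw data — and totals are recomputed afterwards, which also
makes the filter idempotent. `prefilter_low_fraction()` is the separate
differential-splicing pre-filter: it removes features below 5% usage in
*every* sample.

## The simulator

`simulate_null()` / `simulate_dtu()` draw, for every gene and sample,
proportions from $\mathrm{Dirichlet}(\gamma_+\pi_0)$ and counts from
$\mathrm{Multinomial}(m, \cdot)$ — exactly the generative model. Defaults
mirror the small-sample calibration design: $m = 1000$, $q = 3$ or 10
features, 3 vs 3 samples, 1000 genes, common $\gamma_+ = 100$. Proportions
are uniform, geometrically decaying with ratio $0.5$ (a declared stand-in
for the unparameterized "decaying" shape), or explicit. The genewise
architecture draws $\log_{10}\gamma_+$ uniformly on $[1, 3]$ per gene,
standing in for dispersions estimated from real data. Differential genes
swap the two most abundant proportions in the second condition; a tied
top pair makes the swap a no-op and the gene is relabelled null.
`simulate_tuqtl()` adds Hardy-Weinberg genotypes drawn independently of
the counts (a global null), except for designated QTL genes whose minor
allele carriers receive the swapped proportions.

Draws use per-gene seed substreams, so a gene's data does not depend on
how many genes precede it. What the simulator does *not* emulate:
quantification uncertainty and read-mapping ambiguity, correlated
transcript structure across genes, expression-dependent dispersion trends,
linkage disequilibrium beyond exact genotype duplication, and covariate
structure. Passing calibration here therefore demonstrates correctness of
the statistical machinery under the model's own assumptions, not
robustness to everything real RNA-seq does.

## Numerical choices and test scale

Summarizing the constants fixed above: proportion floor $10^{-10}$
(reported values), initialization floor $10^{-6}$, BFGS relative tolerance
$10^{-12}$ with at most 1000 iterations; grid $10^0$–$10^6$ in 21 points;
$W = 0.1$; trend window 10% of genes, minimum 50 (falling back to
common-curve moderation below that); LRT failure threshold $-10^{-6}$;
permutations $B = 100$ with +1 smoothing; cis window 5000 bp; carrier
minimum 5 samples.

The automated checks run the full calibration designs at 1000 genes
$\times$ 10 repetitions (10,000 null tests) for the false-positive-rate
and p-value-uniformity assertions, 100 genes $\times$ 10 repetitions for
the estimator-ordering comparisons (Cox-Reid vs raw profile likelihood,
moderated vs unmoderated), 200,000 draws for the moment identities, and
100 genes $\times$ 100 permutations for the QTL global-null calibration —
sizes chosen to keep Monte-Carlo error well inside the asserted 3-standard-
error tolerances.

## Known limitations

Regression-style designs with covariates are not supported — groups are
categorical. The chi-squared reference for the likelihood-ratio test is
asymptotic and is demonstrably anti-conservative for many features with
decaying proportions, even at the true concentration; with very small
samples and rare isoforms, permutation or stage-wise procedures are more
trustworthy than nominal p-values. Quantification uncertainty is not
propagated. The dispersion grid bounds the estimates; concentrations
genuinely outside $[1, 10^6]$ are reported at the boundary and flagged.
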