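---
title: "Estimating tumor purity from rank-transformed bulk expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor purity from rank-transformed bulk expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A bulk tumor sample is a mixture of malignant cells and the tumor
microenvironment (stroma, immune, endothelial cells). Writing $p$ for the
purity — the malignant fraction — and $C$, $S$ for the expression profiles of
the two compartments, bulk expression is, to first order, the linear mixture
$x = p\,C + (1-p)\,S$. Genes whose expression differs consistently between
the two compartments across tumor types therefore carry a monotone purity
signal, and a sparse linear model on suitably normalized expression can read
$p$ back off.

Two assumptions do all the work:

* **Conserved compartment signatures.** The cancer-vs-stroma contrast of the
  informative genes is broadly conserved across solid tumor types, while
  type-specific expression differences act as nuisance variation. The
  selection machinery (cancer types as cross-validation folds, type-balanced
  subsampling) is designed to keep genes whose association generalizes
  across types and to reject type-private confounds.
* **Monotone comparability.** Only the within-sample ordering of expression
  values is trusted, not their scale. All features are sample-wise
  rank percentiles: ranks ascending with ties assigned the lowest possible
  rank, divided by the number of universe genes observed in the sample
  (`rank_percentile_transform()`). Predictions are thus invariant to any
  per-sample positive monotone rescaling — TPM vs FPKM, library size,
  platform effects that preserve ordering.

Supervision is *weak*: no gold-standard purities exist at cohort scale, so
labels are a consensus of several genomics-based estimators
(`build_consensus()`), which are themselves noisy and disagree. The
consensus pipeline runs, in a fixed order:

1. `flag_extremes()` — per-method estimates below 0.1 or above 0.98 are
   treated as failures and masked (strict inequalities; the bounds are the
   conventional reliability limits of DNA-based callers);
2. `impute_missing_ipca()` — masked cells are completed by iterative PCA
   (see *Numerical choices*);
3. `quantile_normalize_by_group()` — the per-method distributions are
   quantile-normalized within each cancer type, removing method-specific
   calibration differences while preserving each method's ranking;
4. `consensus_purity()` — the sample-wise median (mean available) across
   methods, clipped to $[0,1]$.

This order is deliberate: flagging must precede imputation (otherwise
failures leak into the low-rank fit), and normalization must see complete
columns.

## Feature selection

`select_features()` implements a two-step lasso strategy, with cancer types
as cross-validation folds throughout (leave-one-type-out), so the selected
penalty rewards generalization to *unseen tumor types* rather than unseen
samples of the same types:

* **Step 1, purity-range robustness.** Within each cancer type the top 20%
  of samples by purity are dropped and a lasso is fitted; likewise for the
  bottom 20%. The two gene sets are intersected, keeping genes informative
  in both the low- and high-purity regimes rather than only at the extremes.
  The 20% trim is applied per cancer type (purity distributions differ
  markedly between types); a pan-cohort trim is available
  (`pan_cancer_trim`).
* **Step 2, cancer-type balance.** Restricted to the step-1 genes, one
  subsample drawing the same number of samples from every type — stratified
  by within-type purity deciles with largest-remainder allocation
  (`balanced_subsample()`) — is fitted with the same grouped CV, and the
  final refit at the CV-chosen penalty defines the feature set. Balancing
  stops large cohorts from dominating the penalty choice. The subsample
  size defaults to the smallest type's size (`balance_size = "auto"`).

Step 2 could be organized in several ways (re-subsampling per fold,
accumulating fold-wise selections); this package realizes it as
leave-one-type-out CV on a single balanced subsample followed by one final
refit — the simplest scheme with the intended balancing behavior. Step 1 is
run without balanced subsampling: the range trims already reshape the
per-type purity distributions, and balancing is deferred to the step whose
purpose it is.

The final model (`train_purity_model()`) is unregularized OLS on the
selected features: sparsity has already been enforced, and an unpenalized
fit avoids shrinkage bias in the predictions. Per-feature medians of the
training rank percentiles are stored; at prediction time
(`predict.purity_model()`) feature genes absent from the input are imputed
at those medians, and out-of-range predictions are clipped to the nearest
bound of $[0,1]$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `expr_threshold`, `var_threshold` | 1, 1 | a gene is dropped only if its median expression (linear units) is below the first *and* its variance below the second in every cancer type |
| `low`, `high` (flagging) | 0.1, 0.98 | strict reliability bounds on per-method purity estimates |
| `n_components` | 2 | rank of the iterative-PCA completion; must be below the number of methods |
| `trim_fraction` | 0.20 | per-type purity tail dropped in each step-1 fit |
| `balance_size` | `"auto"` | per-type draw in step 2; `"auto"` = smallest type |
| `nlambda`, `lambda_min_ratio` | 50, 1e-4 | lasso penalty path: 50 log-spaced values spanning four decades below the smallest penalty that zeroes every coefficient |
| `top_fraction`, `bottom_fraction` | 0.2, 0.2 | feature-correlation tails used in single-cell validation |

## The synthetic-data generator

`make_cohort()` generates the linear-mixture structure the model assumes:
per cancer type a cancer and a stromal reference are built from a shared
log-normal baseline; a designated informative-gene set receives a conserved
cancer-vs-stroma fold change (half up in cancer, half up in stroma); all
other genes receive independent per-type log-normal perturbations of both
references — type-private cancer–stroma differences with no consistent
direction, the confound the grouped CV exists to reject. Sample expression
is the mixture at a Beta-distributed purity (type-specific means spanning
0.35–0.72, mirroring the imbalance of real cohorts) times multiplicative
log-normal measurement noise (expression is positive and heteroscedastic;
additive Gaussian noise is available by flag).

Generator defaults and their reasoning:

* `informative_fold = 2`: at the default noise (`noise_sd = 0.1`) this puts
  each informative gene's within-type purity-expression correlation around
  0.6–0.8, the regime of real purity-associated genes in bulk tumors. Much
  larger folds would make every informative gene a near-deterministic
  readout of purity — statistically near-duplicate features, which real
  marker panels are not.
* `group_effect_sd = 0.15`: keeps type-specific perturbations subordinate
  to the conserved cancer-vs-stroma log-offset ($\pm0.35$ at fold 2),
  matching the conserved-signature assumption above.
* `purity_concentration = 8`: within-type purity standard deviation around
  0.17, comparable to real per-type spreads.
* `make_purity_estimates()`: four pseudo-callers with noise sd 0.08,
  per-method biases uniform in $\pm 0.05$, 5% extreme corruptions and 3%
  missing cells — roughly the disagreement level of real DNA-based callers.
* `make_single_cell()`: cells drawn around one type's cancer or stromal
  reference with log-sd 0.4 cell noise and 60% dropout, the single-cell
  analog of the bulk mixture.

What the generator does **not** emulate: real gene-level expression
distributions, gene–gene co-expression beyond the single purity factor,
library-size and batch effects, continuum cell states between malignant and
stromal compartments, or doublets in the single-cell data. Passing tests on
this generator therefore demonstrate the pipeline's correctness and its
behavior under the model's own assumptions — not performance on real
tumors.

## Numerical choices

* **Rank percentiles** use min-rank ties (no averaging); the denominator is
  the number of universe genes *observed in the sample*, so a complete
  sample's unique maximum maps to exactly 1, while tied maxima map below 1.
  Universe genes absent from an input sample simply do not participate in
  ranking — they are handled by median imputation at the feature stage.
  This is one reading of ranking "relative to the universe" when the input
  covers only part of it; it keeps the transform self-contained per sample.
* **Iterative PCA** initializes missing cells at column means, then
  alternates column-centered SVD reconstruction at rank `n_components` with
  overwriting of the missing cells only, until the largest absolute change
  is below `tol` (1e-6) or `max_iter` (100) iterations. Observed values are
  never altered; imputed values are clipped to $[0,1]$ at the end.
  Imputation runs pan-cohort by default (`per_group_impute` switches to
  within-type), and the component count must be below the number of methods
  — with four methods, rank 2 retains the dominant purity axis plus one
  method-disagreement axis.
* **Quantile normalization** uses the mean-of-sorted-columns reference with
  ties receiving the mean of the tied reference positions
  (`limma::normalizeQuantiles`, the standard construction).
* **Lasso fits** (via `glmnet`) run with `standardize = FALSE`: rank
  percentiles already share the $(0,1]$ scale, and standardizing would
  reweight penalties by tie structure. The CV score is the unweighted mean
  over folds of the held-out mean squared error, so every cancer type
  counts equally regardless of size; the penalty minimizing it is kept.
  Coefficients with $|w| > 10^{-10}$ count as selected (solver noise
  tolerance).
* **OLS** falls back to minimum-norm least squares (SVD pseudo-inverse)
  with a warning when the design is rank-deficient.
* **Wilcoxon signed-rank** comparisons use the exact distribution up to 25
  groups, computed by convolution over doubled ranks (exact even with tied
  differences); beyond that, the normal approximation with continuity
  correction. All-zero difference vectors return $p = 1$ by convention.
* **Single-cell z-scores** are computed per gene across all cells jointly
  (classes pooled): per-class scaling would erase the very difference being
  tested. Genes constant across cells get z = 0.
* **Degenerate inputs**: single-sample cancer types are skipped by the gene
  filter (variance undefined) and passed through by quantile normalization,
  each with a warning; a degenerate purity range in the generator is
  allowed but warned about; a group smaller than the number of strata
  falls back to simple random splitting.
* **Determinism**: every stochastic step takes an explicit seed, and equal
  seeds give byte-identical cohorts, selections and models. Models
  serialize to plain text at 17 significant digits, which round-trips
  doubles exactly, so saved and reloaded models predict bit-identically.

## Scale of the shipped checks

The test suite exercises the full pipeline on generated cohorts of 8 types
× 200 samples × 1000 genes (60 informative) for the end-to-end checks and
smaller cohorts (e.g. 4 × 60 × 150) for unit-level properties — sizes
chosen as the smallest at which the cohort structure (type imbalance,
purity stratification, grouped CV) is meaningfully exercised.

## Known limitations

* Purity-informative genes all proxy the same scalar; on data matching the
  generator's single-factor structure they are substantially
  inter-correlated, and the lasso then recovers an accurate *predictive*
  subset rather than the complete informative set — exact support recovery
  is not a property the selection can guarantee under redundancy, even when
  predictions are near-perfect. Relatedly, because rank percentiles are
  compositional, strong purity shifts in informative genes drag the ranks
  of uninformative genes with them, so a few such genes can enter the
  selection legitimately.
* The model is trained for solid-tumor mixtures; profiles without a
  stromal compartment analog (hematological malignancies, cell lines) are
  outside its assumptions.
* The consensus labels inherit any bias shared by all contributing
  genomics estimators; the pipeline removes method-specific calibration,
  not common-mode error.
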