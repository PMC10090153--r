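#' Configuration for two-step lasso feature selection
#'
#' @param trim_fraction fraction of each cancer type's highest- (or lowest-)
#'   purity samples removed before a range-restricted fit; strictly between 0
#'   and 0.5 (default 0.20).
#' @param balance_size samples drawn per cancer type in balanced subsampling;
#'   `"auto"` (default) uses the size of the smallest group.
#' @param nlambda number of lasso penalties on the regularization path
#'   (default 50).
#' @param lambda_min_ratio smallest penalty as a fraction of the
#'   maximum-correlation penalty (default 1e-4, i.e. four decades).
#' @param pan_cancer_trim compute the purity-range trim pan-cancer instead of
#'   per cancer type (default `FALSE`: per cancer type).
#' @param seed integer seed used by the balanced subsampling.
#' @return a `selection_config` list.
#' @export
selection_config <- function(trim_fraction = 0.20, balance_size = "auto",
                             nlambda = 50L, lambda_min_ratio = 1e-4,
                             pan_cancer_trim = FALSE, seed = 1L) {
  stopifnot(trim_fraction > 0, trim_fraction < 0.5)
  if (!identical(balance_size, "auto"))
    stopifnot(is.numeric(balance_size), balance_size >= 10)
  structure(list(trim_fraction = trim_fraction, balance_size = balance_size,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 pan_cancer_trim = isTRUE(pan_cancer_trim),
                 seed = as.integer(seed)),
            class = "selection_config")
}

# Leave-one-group-out cross-validated lasso over a glmnet penalty path.
# Folds are the cancer-type groups; the CV score is the mean over folds of
# the held-out mean squared error, so every cancer type counts equally
# regardless of size. Returns the full-data path fit, the selected penalty,
# and its coefficients.
grouped_cv_lasso <- function(x, y, foldid, nlambda = 50L,
                             lambda_min_ratio = 1e-4) {
  full <- glmnet::glmnet(x, y, alpha = 1, standardize = FALSE,
                         nlambda = nlambda, lambda.min.ratio = lambda_min_ratio)
  lambda <- full$lambda
  folds <- sort(unique(foldid))
  cv_mse <- matrix(NA_real_, length(folds), length(lambda))
  for (i in seq_along(folds)) {
    hold <- foldid == folds[i]
    fit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold], alpha = 1,
                          standardize = FALSE, lambda = lambda)
    pred <- predict(fit, x[hold, , drop = FALSE], s = lambda)
    cv_mse[i, ] <- colMeans((pred - y[hold])^2)
  }
  cvm <- colMeans(cv_mse)
  lambda_min <- lambda[which.min(cvm)]
  beta <- as.numeric(coef(full, s = lambda_min))
  names(beta) <- c("(Intercept)", colnames(x))
  list(fit = full, lambda = lambda, cvm = cvm, lambda_min = lambda_min,
       beta = beta)
}

nonzero_genes <- function(beta, tol = 1e-10) {
  w <- beta[-1]
  names(w)[abs(w) > tol]
}

#' Lasso selection restricted to one purity range
#'
#' Drops the top (or bottom) `trim_fraction` of samples by purity within each
#' cancer type, then fits a lasso of purity on rank-percentile features with
#' leave-one-cancer-type-out cross-validation; the penalty minimising the
#' mean CV error is chosen and the model refit on all retained samples.
#' Genes with non-zero coefficients are returned.
#'
#' @param ranks rank-percentile matrix from [rank_percentile_transform()].
#' @param purity named consensus purity labels.
#' @param groups cancer-type label per sample.
#' @param exclude which purity tail to drop: `"top"` or `"bottom"`.
#' @param cfg a [selection_config()].
#' @return character vector of selected gene identifiers.
#' @export
range_restricted_lasso <- function(ranks, purity, groups,
                                   exclude = c("top", "bottom"),
                                   cfg = selection_config()) {
  exclude <- match.arg(exclude)
  purity <- align_samples(purity, rownames(ranks), "purity")
  groups <- align_samples(groups, rownames(ranks), "groups")
  keep <- character(0)
  trim_sets <- if (cfg$pan_cancer_trim) list(rownames(ranks)) else
    split(rownames(ranks), groups)
  for (ids in trim_sets) {
    n_drop <- floor(cfg$trim_fraction * length(ids))
    if (n_drop > 0) {
      ord <- order(purity[ids], decreasing = (exclude == "top"))
      ids <- ids[ord][-seq_len(n_drop)]
    }
    keep <- c(keep, ids)
  }
  keep <- rownames(ranks)[rownames(ranks) %in% keep]
  g_keep <- groups[keep]
  if (length(unique(g_keep)) < 2) stop("group CV requires >= 2 cancer types")
  res <- grouped_cv_lasso(ranks[keep, , drop = FALSE], purity[keep],
                          as.integer(factor(g_keep)),
                          cfg$nlambda, cfg$lambda_min_ratio)
  nonzero_genes(res$beta)
}

#' Step 1: intersect the two range-restricted selections
#'
#' Runs [range_restricted_lasso()] once excluding the top purity tail and
#' once excluding the bottom tail, and intersects the two gene sets, keeping
#' features relevant in both the low- and high-purity regimes.
#'
#' @inheritParams range_restricted_lasso
#' @return character vector of genes selected in both fits.
#' @export
step1_intersect <- function(ranks, purity, groups, cfg = selection_config()) {
  no_top <- range_restricted_lasso(ranks, purity, groups, "top", cfg)
  no_bottom <- range_restricted_lasso(ranks, purity, groups, "bottom", cfg)
  both <- intersect(no_top, no_bottom)
  if (length(both) == 0)
    stop(sprintf("empty intersection of range-restricted selections (%d and %d genes)",
                 length(no_top), length(no_bottom)))
  both
}

#' Cancer-type-balanced, purity-stratified subsample
#'
#' Draws exactly `balance_size` samples from every cancer type, stratified by
#' within-group purity deciles with proportional largest-remainder
#' allocation, so each group contributes equally while its purity
#' distribution is preserved.
#'
#' @param sample_ids candidate sample identifiers.
#' @param purity named purity values covering `sample_ids`.
#' @param groups cancer-type labels covering `sample_ids`.
#' @param balance_size samples to draw per group; must not exceed the
#'   smallest group.
#' @param seed integer seed; identical seeds give identical draws.
#' @return character vector of drawn sample ids.
#' @export
balanced_subsample <- function(sample_ids, purity, groups, balance_size, seed) {
  purity <- align_samples(purity, sample_ids, "purity")
  groups <- align_samples(groups, sample_ids, "groups")
  sizes <- table(groups)
  if (balance_size > min(sizes))
    stop(sprintf("balance_size %d exceeds smallest group (%d)",
                 balance_size, min(sizes)))
  set.seed(seed)
  out <- character(0)
  for (g in sort(unique(groups))) {
    ids <- sample_ids[groups == g]
    if (length(ids) == balance_size) { out <- c(out, ids); next }
    strat <- rank_strata(purity[ids], 10L)
    take <- allocate_proportional(tabulate(strat), balance_size)
    for (s in seq_along(take)) {
      in_s <- ids[strat == s]
      out <- c(out, if (take[s] >= length(in_s)) in_s else sample(in_s, take[s]))
    }
  }
  out
}

#' Step 2: balanced refinement of the step-1 gene set
#'
#' Restricts the features to the step-1 genes, draws one cancer-type-balanced
#' purity-stratified subsample spanning all purity ranges, and fits a lasso
#' with leave-one-cancer-type-out cross-validation on it; the final model is
#' the refit on that subsample at the CV-selected penalty. Genes with
#' non-zero weight form the feature set, annotated with each gene's mean
#' per-cancer-type Pearson correlation between rank-percentile expression and
#' purity, computed on the full training data.
#'
#' @inheritParams range_restricted_lasso
#' @param step1_genes genes surviving [step1_intersect()].
#' @return a `feature_set` data frame with columns `gene_id` and
#'   `mean_correlation`, ordered by decreasing correlation, with attributes
#'   `step1_n` and `step2_n`.
#' @export
step2_refine <- function(ranks, purity, groups, step1_genes,
                         cfg = selection_config()) {
  if (length(step1_genes) == 0) stop("step1_genes is empty")
  purity <- align_samples(purity, rownames(ranks), "purity")
  groups <- align_samples(groups, rownames(ranks), "groups")
  bsize <- if (identical(cfg$balance_size, "auto"))
    min(table(groups)) else cfg$balance_size
  sub <- balanced_subsample(rownames(ranks), purity, groups, bsize, cfg$seed)
  g_sub <- groups[sub]
  if (length(unique(g_sub)) < 2) stop("group CV requires >= 2 cancer types")
  res <- grouped_cv_lasso(ranks[sub, step1_genes, drop = FALSE], purity[sub],
                          as.integer(factor(g_sub)),
                          cfg$nlambda, cfg$lambda_min_ratio)
  genes <- nonzero_genes(res$beta)
  if (length(genes) == 0) stop("no genes retained by the step-2 refinement")
  cors <- mean_group_correlation(ranks[, genes, drop = FALSE], purity, groups)
  feature_set(genes, cors[genes], step1_n = length(step1_genes),
              step2_n = length(genes))
}

# Mean over cancer types of the within-type Pearson correlation between each
# gene's rank percentile and purity.
mean_group_correlation <- function(ranks, purity, groups) {
  per_group <- sapply(unique(groups), function(g) {
    idx <- groups == g
    suppressWarnings(cor(ranks[idx, , drop = FALSE], purity[idx]))
  })
  rowMeans(matrix(per_group, nrow = ncol(ranks),
                  dimnames = list(colnames(ranks), NULL)), na.rm = TRUE)
}

feature_set <- function(genes, correlations, step1_n = NA_integer_,
                        step2_n = length(genes)) {
  ord <- order(correlations, decreasing = TRUE)
  structure(data.frame(gene_id = genes[ord],
                       mean_correlation = unname(correlations[ord]),
                       stringsAsFactors = FALSE),
            step1_n = step1_n, step2_n = step2_n,
            class = c("feature_set", "data.frame"))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d genes (step 1: %s candidates)\n",
              nrow(x), attr(x, "step1_n")))
  print.data.frame(head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Two-step lasso feature selection
#'
#' Convenience wrapper running [step1_intersect()] followed by
#' [step2_refine()].
#'
#' @inheritParams range_restricted_lasso
#' @return a `feature_set` (see [step2_refine()]).
#' @export
select_features <- function(ranks, purity, groups, cfg = selection_config()) {
  step1 <- step1_intersect(ranks, purity, groups, cfg)
  step2_refine(ranks, purity, groups, step1, cfg)
}

#' Write / read a feature set as TSV
#' @param features a `feature_set`.
#' @param path file path.
#' @export
write_feature_set <- function(features, path) {
  df <- data.frame(gene_id = features$gene_id,
                   mean_correlation = sprintf("%.17g", features$mean_correlation))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  feature_set(df$gene_id, setNames(as.numeric(df$mean_correlation), df$gene_id))
}
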