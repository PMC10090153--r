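#' Sample-wise rank-percentile transformation
#'
#' Replaces each sample's expression values by ascending-rank percentiles,
#' making downstream models invariant to measurement units and per-sample
#' scale (TPM vs FPKM, library size, platform). Within a sample, values are
#' ranked ascending with the lowest possible rank assigned to tied groups
#' (min-rank), and the percentile is the rank divided by the number of
#' universe genes observed in that sample. For example a sample measuring
#' `[0, 0, 1, 5, 100]` over a five-gene universe gets ranks `[1, 1, 3, 4, 5]`
#' and percentiles `[0.2, 0.2, 0.6, 0.8, 1]`.
#'
#' Genes of `expr` outside the universe are dropped before ranking; universe
#' genes absent from `expr` contribute nothing here and are median-imputed at
#' prediction time (see [predict.purity_model()]). Masked (`NA`) entries stay
#' `NA` and do not count towards the percentile denominator.
#'
#' @param expr numeric matrix, samples in rows, genes in columns, linear-scale
#'   non-negative expression values (TPM/FPKM/counts).
#' @param universe character vector of gene identifiers defining the ranking
#'   universe (e.g. the output of [filter_genes()]).
#' @return numeric matrix of rank percentiles in `(0, 1]`, samples in rows,
#'   with columns the universe genes present in `expr` (in universe order) and
#'   the full universe attached as `attr(, "universe")`.
#' @examples
#' x <- matrix(c(0, 0, 1, 5, 100), nrow = 1,
#'             dimnames = list("s1", paste0("g", 1:5)))
#' rank_percentile_transform(x, paste0("g", 1:5))
#' @export
rank_percentile_transform <- function(expr, universe) {
  check_expression(expr, allow_na = TRUE)
  universe <- strip_ws(universe)
  if (length(universe) == 0) stop("universe is empty")
  if (anyDuplicated(universe)) stop("universe gene identifiers must be unique")
  colnames(expr) <- strip_ws(colnames(expr))
  keep <- universe[universe %in% colnames(expr)]
  if (length(keep) == 0) stop("no universe genes present in the expression matrix")
  x <- expr[, keep, drop = FALSE]
  out <- t(apply(x, 1, function(v) {
    n_obs <- sum(!is.na(v))
    if (n_obs == 0) return(rep(NA_real_, length(v)))
    rank(v, ties.method = "min", na.last = "keep") / n_obs
  }))
  dimnames(out) <- list(rownames(x), keep)
  attr(out, "universe") <- universe
  out
}

#' Build a gene universe by filtering low-expression, low-variance genes
#'
#' A gene is removed only if it has both low median expression
#' (`median < expr_threshold`) and low variance (`variance < var_threshold`)
#' in every cohort group (cancer type); equivalently it is kept if in at
#' least one group it passes either criterion. The thresholds default to a
#' median of 1 (TPM-scale) and a variance of 1. An optional allow-list (for
#' example autosomal protein-coding genes) restricts the result further.
#'
#' @param expr numeric samples x genes matrix in linear units.
#' @param groups cancer-type label per sample (named by sample or in row
#'   order).
#' @param expr_threshold,var_threshold non-negative filter thresholds.
#' @param allow_list optional character vector; when given, only genes in it
#'   are eligible.
#' @return character vector of retained gene identifiers (the universe), in
#'   the column order of `expr`.
#' @export
filter_genes <- function(expr, groups, expr_threshold = 1, var_threshold = 1,
                         allow_list = NULL) {
  check_expression(expr)
  stopifnot(expr_threshold >= 0, var_threshold >= 0)
  groups <- align_samples(groups, rownames(expr), "groups")
  qualifies <- rep(FALSE, ncol(expr))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning(sprintf("group '%s' has < 2 samples; variance undefined, group skipped", g))
      next
    }
    sub <- expr[idx, , drop = FALSE]
    med <- apply(sub, 2, median)
    v <- apply(sub, 2, var)
    qualifies <- qualifies | (med >= expr_threshold) | (v >= var_threshold)
  }
  genes <- colnames(expr)[qualifies]
  if (!is.null(allow_list)) genes <- genes[genes %in% strip_ws(allow_list)]
  if (length(genes) == 0) stop("no genes pass the filter")
  genes
}

#' Purity- and cancer-type-stratified train/test split
#'
#' Splits samples into disjoint train and test sets so that each cancer type
#' contributes proportionally and, within each cancer type, the purity
#' distribution is preserved (assignment stratified by within-group purity
#' deciles with largest-remainder allocation). Groups smaller than the number
#' of strata fall back to a simple random split with a warning.
#'
#' @param purity per-sample purity label in `[0, 1]` (named by sample).
#' @param groups cancer-type label per sample.
#' @param train_fraction fraction of each group assigned to training
#'   (strictly between 0 and 1).
#' @param n_strata number of purity strata per group (default deciles).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(purity, groups, train_fraction = 0.8,
                             n_strata = 10L, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (is.null(names(purity))) stop("`purity` must be named by sample")
  groups <- align_samples(groups, names(purity), "groups")
  if (anyNA(purity)) stop("every sample needs a purity label")
  set.seed(seed)
  train <- character(0)
  for (g in unique(groups)) {
    ids <- names(purity)[groups == g]
    n_g <- length(ids)
    n_train <- round(train_fraction * n_g)
    if (n_g < n_strata) {
      warning(sprintf("group '%s' smaller than %d strata; simple random split used",
                      g, n_strata))
      train <- c(train, sample(ids, n_train))
      next
    }
    strat <- rank_strata(purity[ids], n_strata)
    sizes <- tabulate(strat)
    take <- allocate_proportional(sizes, n_train)
    for (s in seq_along(sizes)) {
      in_s <- ids[strat == s]
      train <- c(train, if (take[s] >= length(in_s)) in_s else sample(in_s, take[s]))
    }
  }
  list(train = train, test = setdiff(names(purity), train))
}
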