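#' Fit the full purity pipeline on a training cohort
#'
#' Convenience wrapper chaining the training stages: gene-universe filtering,
#' sample-wise rank-percentile transformation, two-step lasso feature
#' selection, and the final ordinary least-squares fit on the full training
#' split. Labels may be given directly (`purity`) or as a raw multi-method
#' estimate table (`estimates`), in which case consensus labels are built
#' first.
#'
#' @param expr training samples x genes matrix in linear units.
#' @param groups cancer-type label per sample.
#' @param purity named consensus purity labels; omit when `estimates` given.
#' @param estimates samples x methods purity-estimate matrix (`NA` missing);
#'   consensus labels are derived via [build_consensus()].
#' @param expr_threshold,var_threshold gene-filter thresholds (see
#'   [filter_genes()]).
#' @param allow_list optional gene allow-list for the universe.
#' @param cfg a [selection_config()].
#' @return list with the fitted `model` (a `purity_model`), the `universe`,
#'   the selected `features`, and the `purity` labels used.
#' @export
fit_purity_pipeline <- function(expr, groups, purity = NULL, estimates = NULL,
                                expr_threshold = 1, var_threshold = 1,
                                allow_list = NULL, cfg = selection_config()) {
  if (is.null(purity)) {
    if (is.null(estimates)) stop("provide either `purity` or `estimates`")
    purity <- build_consensus(estimates, groups)
  }
  keep <- intersect(rownames(expr), names(purity))
  expr <- expr[keep, , drop = FALSE]
  groups <- align_samples(groups, keep, "groups")
  purity <- purity[keep]
  universe <- filter_genes(expr, groups, expr_threshold, var_threshold,
                           allow_list)
  ranks <- rank_percentile_transform(expr, universe)
  features <- select_features(ranks, purity, groups, cfg)
  model <- train_purity_model(ranks, purity, features,
                              metadata = list(seed = cfg$seed,
                                              groups = as.list(table(groups))))
  list(model = model, universe = universe, features = features,
       purity = purity)
}
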