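#' Per-cancer-type Pearson correlation and RMSE
#'
#' Scores predicted against reference purities within each cancer-type
#' group, on the intersection of samples, and summarizes across groups with
#' medians, means and inter-quartile ranges. Groups with fewer than two
#' overlapping samples are skipped with a warning; a group with
#' zero-variance predictions gets an undefined (`NA`) correlation but its
#' RMSE is still reported.
#'
#' @param pred named numeric vector of predicted purities (or the data frame
#'   returned by [predict.purity_model()]).
#' @param truth named numeric vector of reference purities.
#' @param groups cancer-type label per sample.
#' @return a `purity_eval` list: `per_group` data frame (`group`, `n`,
#'   `pearson_r`, `rmse`) and `summary` (medians, means, IQRs).
#' @export
score_predictions <- function(pred, truth, groups) {
  if (is.data.frame(pred)) pred <- setNames(pred$purity, pred$sample_id)
  ids <- intersect(names(pred), names(truth))
  if (length(ids) == 0) stop("no overlapping samples between pred and truth")
  groups <- align_samples(groups, ids, "groups")
  rows <- list()
  for (g in sort(unique(groups))) {
    in_g <- ids[groups == g]
    if (length(in_g) < 2) {
      warning(sprintf("group '%s' has < 2 overlapping samples; skipped", g))
      next
    }
    p <- pred[in_g]; t <- truth[in_g]
    r <- if (sd(p) == 0 || sd(t) == 0) {
      warning(sprintf("zero variance in group '%s'; correlation undefined", g))
      NA_real_
    } else cor(p, t)
    rows[[g]] <- data.frame(group = g, n = length(in_g), pearson_r = r,
                            rmse = rmse(p, t), stringsAsFactors = FALSE)
  }
  per_group <- do.call(rbind, rows)
  rownames(per_group) <- NULL
  structure(list(
    per_group = per_group,
    summary = list(
      median_r = median(per_group$pearson_r, na.rm = TRUE),
      median_rmse = median(per_group$rmse),
      mean_r = mean(per_group$pearson_r, na.rm = TRUE),
      mean_rmse = mean(per_group$rmse),
      iqr_r = unname(diff(quantile(per_group$pearson_r, c(0.25, 0.75),
                                   na.rm = TRUE))),
      iqr_rmse = unname(diff(quantile(per_group$rmse, c(0.25, 0.75)))))),
    class = "purity_eval")
}

#' @export
print.purity_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d groups: median r = %.3f, median RMSE = %.3f\n",
              nrow(x$per_group), x$summary$median_r, x$summary$median_rmse))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two evaluations across cancer types
#'
#' Compares the per-group metric of two model evaluations with a two-tailed
#' Wilcoxon signed-rank test over the common groups, and reports the
#' difference between the metric medians. The exact signed-rank distribution
#' is used up to 25 groups, the normal approximation with continuity
#' correction above. When every per-group difference is zero the p-value is
#' 1 by convention (with a warning).
#'
#' @param report_a,report_b `purity_eval` objects covering the same groups.
#' @param metric `"r"` (Pearson correlation) or `"rmse"`.
#' @return list with `statistic`, `p_value` (two-tailed),
#'   `delta_of_medians` (`median_a - median_b`) and `n_groups`.
#' @export
paired_compare <- function(report_a, report_b, metric = c("r", "rmse")) {
  metric <- match.arg(metric)
  col <- if (metric == "r") "pearson_r" else "rmse"
  a <- setNames(report_a$per_group[[col]], report_a$per_group$group)
  b <- setNames(report_b$per_group[[col]], report_b$per_group$group)
  common <- intersect(names(a), names(b))
  if (length(common) < length(a) || length(common) < length(b))
    warning("reports cover different groups; restricted to the intersection")
  a <- a[common]; b <- b[common]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  delta <- median(a) - median(b)
  if (all(a == b)) {
    warning("all per-group differences are zero; p = 1 by convention")
    return(list(statistic = NA_real_, p_value = 1, delta_of_medians = delta,
                n_groups = n))
  }
  d <- a - b
  if (any(d == 0)) {
    warning(sprintf("%d zero difference(s) dropped from the signed-rank test",
                    sum(d == 0)))
    d <- d[d != 0]
  }
  if (length(d) <= 25) {
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    p <- exact_signed_rank_p(d)
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                  exact = FALSE, correct = TRUE))
    v <- unname(wt$statistic)
    p <- wt$p.value
  }
  list(statistic = v, p_value = p, delta_of_medians = delta, n_groups = n)
}

# Exact two-tailed signed-rank p-value from the full distribution of the
# statistic over all 2^n sign assignments, computed by convolution over the
# doubled (hence integer, even with average-rank ties) rank weights.
exact_signed_rank_p <- function(d) {
  r <- rank(abs(d))
  v2 <- round(2 * sum(r[d > 0]))
  w <- as.integer(round(2 * r))
  probs <- 1
  for (wi in w) probs <- (c(probs, rep(0, wi)) + c(rep(0, wi), probs)) / 2
  p_ge <- sum(probs[(v2 + 1):length(probs)])
  p_le <- sum(probs[seq_len(v2 + 1)])
  min(1, 2 * min(p_ge, p_le))
}

#' Validate a feature set on labeled single-cell data
#'
#' Splits the model's feature genes into the top and bottom fractions by
#' mean purity-expression correlation, z-scores each gene across all cells
#' jointly (malignant and non-malignant pooled, so the two classes share a
#' scale), computes each cell's mean z over the two gene groups, and
#' compares malignant against non-malignant cells with a two-tailed
#' Mann-Whitney U test for each group. If the features discriminate, cells
#' of the malignant class score higher on positively correlated genes and
#' lower on negatively correlated genes.
#'
#' @param expr cells x genes expression matrix (a `synthetic_single_cell`'s
#'   `$expr` or a real matrix).
#' @param cell_labels per-cell labels; entries equal to `malignant_label`
#'   form the malignant class.
#' @param features a `feature_set` with `mean_correlation` annotations.
#' @param top_fraction,bottom_fraction fractions of features (by
#'   correlation) forming the positive and negative gene groups (default
#'   0.2 each).
#' @param malignant_label label value marking malignant cells (default
#'   `"malignant"`).
#' @return an `sc_validation` list: `scores` data frame (`cell_id`,
#'   `label`, `z_positive`, `z_negative`), `p_positive`, `p_negative`
#'   (two-tailed Mann-Whitney), per-class medians, and the two gene groups.
#' @export
single_cell_validation <- function(expr, cell_labels, features,
                                   top_fraction = 0.2, bottom_fraction = 0.2,
                                   malignant_label = "malignant") {
  check_expression(expr, arg = "expr")
  cell_labels <- align_samples(cell_labels, rownames(expr), "cell_labels")
  if (anyNA(features$mean_correlation))
    stop("features must carry mean purity-expression correlations")
  ord <- order(features$mean_correlation, decreasing = TRUE)
  n <- nrow(features)
  pos_genes <- features$gene_id[ord][seq_len(max(1, round(top_fraction * n)))]
  neg_genes <- rev(features$gene_id[ord])[seq_len(max(1, round(bottom_fraction * n)))]
  missing <- setdiff(c(pos_genes, neg_genes), colnames(expr))
  if (length(missing) > 0)
    stop(sprintf("feature genes absent from the cell matrix: %s",
                 paste(missing, collapse = ", ")))

  zscore <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    s[s == 0] <- 1  # constant genes carry no signal; z fixed at 0
    sweep(sweep(m, 2, mu), 2, s, `/`)
  }
  z_pos <- rowMeans(zscore(expr[, pos_genes, drop = FALSE]))
  z_neg <- rowMeans(zscore(expr[, neg_genes, drop = FALSE]))
  mal <- cell_labels == malignant_label
  if (!any(mal) || all(mal)) stop("both cell classes must be non-empty")
  p_pos <- wilcox.test(z_pos[mal], z_pos[!mal], alternative = "two.sided")$p.value
  p_neg <- wilcox.test(z_neg[mal], z_neg[!mal], alternative = "two.sided")$p.value
  structure(list(
    scores = data.frame(cell_id = rownames(expr),
                        label = unname(cell_labels),
                        z_positive = unname(z_pos),
                        z_negative = unname(z_neg),
                        stringsAsFactors = FALSE),
    p_positive = p_pos, p_negative = p_neg,
    medians = list(
      positive = c(malignant = median(z_pos[mal]),
                   non_malignant = median(z_pos[!mal])),
      negative = c(malignant = median(z_neg[mal]),
                   non_malignant = median(z_neg[!mal]))),
    gene_groups = list(positive = pos_genes, negative = neg_genes)),
    class = "sc_validation")
}

#' @export
print.sc_validation <- function(x, ...) {
  cat("Single-cell feature validation\n")
  cat(sprintf("  positive-correlation genes (%d): malignant median z %.3f vs non-malignant %.3f, p = %.3g\n",
              length(x$gene_groups$positive), x$medians$positive["malignant"],
              x$medians$positive["non_malignant"], x$p_positive))
  cat(sprintf("  negative-correlation genes (%d): malignant median z %.3f vs non-malignant %.3f, p = %.3g\n",
              length(x$gene_groups$negative), x$medians$negative["malignant"],
              x$medians$negative["non_malignant"], x$p_negative))
  invisible(x)
}
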