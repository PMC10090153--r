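#' Flag extreme purity estimates as missing
#'
#' Genomics purity callers are unreliable at the extremes of their range;
#' per-method estimates strictly below `low` or strictly above `high` are
#' masked as missing so that they can be re-imputed from the remaining
#' methods. Defaults follow the recommended thresholds of <0.1 and >0.98.
#'
#' @param estimates samples x methods numeric matrix in `[0, 1]`; `NA` =
#'   already missing.
#' @param low,high strict flagging thresholds, `0 <= low < high <= 1`.
#' @return the matrix with flagged entries set to `NA`.
#' @export
flag_extremes <- function(estimates, low = 0.1, high = 0.98) {
  stopifnot(is.matrix(estimates), low >= 0, high <= 1, low < high)
  estimates[!is.na(estimates) & (estimates < low | estimates > high)] <- NA
  estimates
}

#' Impute missing purity estimates by iterative PCA
#'
#' Low-rank matrix completion by EM-style iterative principal component
#' analysis: missing cells are initialised with column means, then the matrix
#' is repeatedly column-centred, approximated at rank `n_components` via SVD,
#' and the reconstruction written back into the missing cells only, until the
#' largest absolute change falls below `tol` or `max_iter` is reached.
#' Observed entries are never altered; imputed values are clipped to
#' `[0, 1]`.
#'
#' @param estimates samples x methods matrix with `NA` missing cells; at
#'   least two methods.
#' @param n_components rank of the PCA reconstruction (must be smaller than
#'   the number of methods; default 2).
#' @param tol convergence tolerance on the imputed cells (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return completed matrix; samples with no observed value at all are
#'   dropped with a warning.
#' @export
impute_missing_ipca <- function(estimates, n_components = 2L, tol = 1e-6,
                                max_iter = 100L) {
  stopifnot(is.matrix(estimates))
  if (ncol(estimates) < 2) stop("imputation needs >= 2 methods")
  if (n_components >= ncol(estimates))
    stop("n_components must be smaller than the number of methods")
  all_na_col <- colSums(!is.na(estimates)) == 0
  if (any(all_na_col))
    stop(sprintf("method has no observations: %s",
                 paste(colnames(estimates)[all_na_col], collapse = ", ")))
  all_na_row <- rowSums(!is.na(estimates)) == 0
  if (any(all_na_row)) {
    warning(sprintf("%d sample(s) with no observed estimate dropped", sum(all_na_row)))
    estimates <- estimates[!all_na_row, , drop = FALSE]
  }
  miss <- is.na(estimates)
  if (!any(miss)) return(estimates)

  cur <- estimates
  col_means <- colMeans(estimates, na.rm = TRUE)
  cur[miss] <- rep(col_means, each = nrow(cur))[miss]
  k <- n_components
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(cur)
    s <- svd(sweep(cur, 2, mu), nu = k, nv = k)
    recon <- s$u %*% (s$d[seq_len(k)] * t(s$v))
    recon <- sweep(recon, 2, mu, `+`)
    delta <- max(abs(cur[miss] - recon[miss]))
    cur[miss] <- recon[miss]
    if (delta < tol) break
  }
  cur[miss] <- clip01(cur[miss])
  cur
}

#' Quantile-normalize purity estimates within each cancer type
#'
#' Standardizes the purity distributions of the different estimation methods
#' separately within each cancer-type group: for each group, the reference
#' distribution is the mean of the per-method sorted value vectors, and each
#' method's values are replaced by the reference value at their rank (tied
#' ranks receive the mean of the tied reference positions). Within-group,
#' per-method rank order is preserved, and after normalization all method
#' columns of a group have identical sorted values.
#'
#' @param estimates samples x methods matrix with no missing values (run
#'   after [impute_missing_ipca()]).
#' @param groups cancer-type label per sample.
#' @return normalized matrix of the same shape. Groups of size 1 are passed
#'   through unchanged with a warning.
#' @export
quantile_normalize_by_group <- function(estimates, groups) {
  stopifnot(is.matrix(estimates))
  if (anyNA(estimates))
    stop("missing values present; impute before quantile normalization")
  groups <- align_samples(groups, rownames(estimates), "groups")
  out <- estimates
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning(sprintf("group '%s' has a single sample; passed through unchanged", g))
      next
    }
    out[idx, ] <- limma::normalizeQuantiles(estimates[idx, , drop = FALSE],
                                            ties = TRUE)
  }
  out
}

#' Reduce a normalized estimate table to consensus purity
#'
#' Per-sample reduction across methods, median by default; the result is
#' clipped to `[0, 1]`.
#'
#' @param estimates samples x methods matrix (flagged, imputed, normalized).
#' @param reducer `"median"` (default) or `"mean"`.
#' @return named numeric vector of consensus purity per sample.
#' @export
consensus_purity <- function(estimates, reducer = c("median", "mean")) {
  reducer <- match.arg(reducer)
  fn <- if (reducer == "median") median else mean
  clip01(apply(estimates, 1, fn, na.rm = TRUE))
}

#' Consensus purity labels from multiple genomics estimates
#'
#' Runs the full label-construction pipeline in its fixed order:
#' flag extremes as missing, impute missing cells by iterative PCA,
#' quantile-normalize per cancer type, and reduce per sample. This order is
#' the only supported composition of the four steps.
#'
#' @param estimates samples x methods matrix of purity estimates in
#'   `[0, 1]`, `NA` = missing.
#' @param groups cancer-type label per sample.
#' @param low,high extreme-value flagging thresholds (see [flag_extremes()]).
#' @param n_components,tol,max_iter imputation parameters (see
#'   [impute_missing_ipca()]).
#' @param per_group_impute impute within each cancer type separately instead
#'   of across the whole cohort (default `FALSE`).
#' @param reducer per-sample reduction, `"median"` (default) or `"mean"`.
#' @return named numeric vector of consensus purities in `[0, 1]` (samples
#'   dropped during imputation are absent).
#' @export
build_consensus <- function(estimates, groups, low = 0.1, high = 0.98,
                            n_components = 2L, tol = 1e-6, max_iter = 100L,
                            per_group_impute = FALSE,
                            reducer = c("median", "mean")) {
  groups <- align_samples(groups, rownames(estimates), "groups")
  flagged <- flag_extremes(estimates, low, high)
  if (per_group_impute) {
    pieces <- lapply(unique(groups), function(g) {
      impute_missing_ipca(flagged[groups == g, , drop = FALSE],
                          n_components, tol, max_iter)
    })
    imputed <- do.call(rbind, pieces)
    imputed <- imputed[intersect(rownames(flagged), rownames(imputed)), , drop = FALSE]
  } else {
    imputed <- impute_missing_ipca(flagged, n_components, tol, max_iter)
  }
  normalized <- quantile_normalize_by_group(imputed, groups[rownames(imputed)])
  consensus_purity(normalized, reducer)
}
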