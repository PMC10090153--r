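new_purity_model <- function(universe, features, weights, intercept,
                             feature_medians, metadata = list()) {
  structure(list(universe = universe, features = features,
                 weights = weights, intercept = intercept,
                 feature_medians = feature_medians, metadata = metadata),
            class = "purity_model")
}

#' @export
print.purity_model <- function(x, ...) {
  cat(sprintf("Purity model: %d features over a %d-gene ranking universe\n",
              length(x$weights), length(x$universe)))
  cat(sprintf("  intercept %.4f; trained on %s samples\n",
              x$intercept, x$metadata$n_samples %||% "?"))
  invisible(x)
}

#' Train the final linear purity predictor
#'
#' Ordinary least-squares fit of consensus purity on the rank-percentile
#' columns of the selected feature genes. Selection (the lasso steps) has
#' already enforced sparsity, so the final model is unregularized. The
#' per-feature medians of the training rank percentiles are stored for
#' prediction-time imputation of genes missing from new data, and the
#' ranking universe travels with the model so prediction-time ranking
#' replicates training exactly.
#'
#' @param ranks training rank-percentile matrix (its `"universe"` attribute,
#'   set by [rank_percentile_transform()], is stored in the model).
#' @param purity named consensus purity labels in `[0, 1]`.
#' @param features a `feature_set` (or character vector of gene ids).
#' @param metadata optional named list recorded in the model (seed, notes).
#' @return a `purity_model`.
#' @export
train_purity_model <- function(ranks, purity, features, metadata = list()) {
  genes <- if (is.character(features)) features else features$gene_id
  missing <- setdiff(genes, colnames(ranks))
  if (length(missing) > 0)
    stop(sprintf("feature genes absent from ranks: %s",
                 paste(head(missing, 3), collapse = ", ")))
  purity <- align_samples(purity, rownames(ranks), "purity")
  x <- ranks[, genes, drop = FALSE]
  if (nrow(x) < length(genes) + 1)
    warning("fewer samples than features + 1; fit may be unstable")
  coefs <- ols_fit(cbind(`(Intercept)` = 1, x), purity)
  fs <- if (is.character(features))
    feature_set(genes, setNames(rep(NA_real_, length(genes)), genes)) else features
  new_purity_model(
    universe = attr(ranks, "universe") %||% colnames(ranks),
    features = fs,
    weights = coefs[genes],
    intercept = coefs[["(Intercept)"]],
    feature_medians = apply(x, 2, median, na.rm = TRUE),
    metadata = c(metadata,
                 list(n_samples = nrow(x), date = as.character(Sys.Date()))))
}

# OLS with a minimum-norm fallback for rank-deficient designs.
ols_fit <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank == ncol(X)) {
    coefs <- qr.coef(qr_x, y)
  } else {
    warning("rank-deficient design; minimum-norm least squares used")
    s <- svd(X)
    pos <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
    coefs <- s$v[, pos, drop = FALSE] %*%
      ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
    coefs <- drop(coefs)
  }
  setNames(as.numeric(coefs), colnames(X))
}

#' Predict tumor purity for unseen samples
#'
#' Three-stage inference: (1) rank-percentile transform of the overlap
#' between the sample's genes and the model's ranking universe; (2)
#' restriction to the model's feature genes, with any feature absent from the
#' input imputed at its training-median rank percentile; (3) linear
#' prediction, with values outside `[0, 1]` rounded to the nearest in-range
#' value.
#'
#' @param object a `purity_model`.
#' @param expr samples x genes matrix in linear units; any overlap with the
#'   model universe is accepted, but a warning is attached when more than
#'   half of the features had to be imputed for some sample.
#' @param ... unused.
#' @return data frame with columns `sample_id`, `purity` and
#'   `n_imputed_features`.
#' @export
predict.purity_model <- function(object, expr, ...) {
  ranks <- rank_percentile_transform(expr, object$universe)
  genes <- names(object$weights)
  n <- nrow(ranks)
  x <- matrix(NA_real_, n, length(genes), dimnames = list(rownames(ranks), genes))
  present <- genes[genes %in% colnames(ranks)]
  x[, present] <- ranks[, present]
  n_imputed <- integer(n)
  for (g in genes) {
    miss <- is.na(x[, g])
    if (any(miss)) {
      x[miss, g] <- object$feature_medians[[g]]
      n_imputed[miss] <- n_imputed[miss] + 1L
    }
  }
  if (length(genes) > 0 && any(n_imputed > 0.5 * length(genes)))
    warning(sprintf("%d sample(s) had > 50%% of model features imputed",
                    sum(n_imputed > 0.5 * length(genes))))
  raw <- drop(x %*% object$weights) + object$intercept
  data.frame(sample_id = rownames(ranks), purity = unname(clip01(raw)),
             n_imputed_features = n_imputed, stringsAsFactors = FALSE)
}

#' Cancer-type-specific lasso models
#'
#' Trains one model per cancer type on the full ranking universe, with the
#' lasso penalty chosen by 5-fold cross-validation within the type.
#'
#' @param ranks rank-percentile matrix over the full universe.
#' @param purity named purity labels.
#' @param groups cancer-type label per sample.
#' @param nfolds folds for within-type cross-validation (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return named list of `purity_model` objects, one per cancer type. Types
#'   with fewer than 20 samples trigger a warning. A type whose features are
#'   all shrunk away yields an intercept-only model predicting its mean
#'   label.
#' @export
train_per_group <- function(ranks, purity, groups, nfolds = 5L, seed = 1L) {
  purity <- align_samples(purity, rownames(ranks), "purity")
  groups <- align_samples(groups, rownames(ranks), "groups")
  universe <- attr(ranks, "universe") %||% colnames(ranks)
  models <- list()
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    if (length(idx) < 20)
      warning(sprintf("group '%s' has %d samples (< 20); model may be unreliable",
                      g, length(idx)))
    x <- ranks[idx, , drop = FALSE]
    y <- purity[idx]
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(x, y, alpha = 1, standardize = FALSE,
                               nfolds = nfolds, type.measure = "mse")
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))
    names(beta) <- c("(Intercept)", colnames(x))
    genes <- nonzero_genes(beta)
    medians <- if (length(genes) > 0)
      apply(x[, genes, drop = FALSE], 2, median) else setNames(numeric(0), genes)
    models[[g]] <- new_purity_model(
      universe = universe,
      features = feature_set(genes, setNames(rep(NA_real_, length(genes)), genes)),
      weights = setNames(beta[genes], genes),
      intercept = beta[["(Intercept)"]],
      feature_medians = medians,
      metadata = list(group = g, n_samples = length(idx),
                      lambda = cvfit$lambda.min, seed = seed,
                      date = as.character(Sys.Date())))
  }
  models
}

#' Leave-one-cancer-type-out models
#'
#' For each cancer type, fits the final linear model on the fixed feature
#' set using all samples of the other types; evaluating model `g` on type
#' `g` measures generalization to tumor types absent from training.
#'
#' @inheritParams train_per_group
#' @param features the fixed `feature_set` of the pan-cancer model.
#' @return named list of `purity_model` objects; model `g` was trained
#'   without group `g`.
#' @export
train_leave_one_group_out <- function(ranks, purity, groups, features) {
  purity <- align_samples(purity, rownames(ranks), "purity")
  groups <- align_samples(groups, rownames(ranks), "groups")
  if (length(unique(groups)) < 2) stop("need >= 2 cancer types")
  universe <- attr(ranks, "universe") %||% colnames(ranks)
  models <- list()
  for (g in sort(unique(groups))) {
    idx <- which(groups != g)
    sub <- ranks[idx, , drop = FALSE]
    attr(sub, "universe") <- universe
    models[[g]] <- train_purity_model(sub, purity[idx], features,
                                      metadata = list(withheld_group = g))
  }
  models
}

#' Save / load a purity model as a plain-text archive
#'
#' The model is written to a directory holding a JSON manifest (intercept,
#' metadata), a TSV weight table (gene, weight, training-median rank
#' percentile, mean purity correlation) and the ranking universe, all at
#' full double precision so that a save/load round trip reproduces
#' predictions bit-identically.
#'
#' @param model a `purity_model`.
#' @param path directory to create or read.
#' @return `load_purity_model` returns the restored `purity_model`.
#' @export
save_purity_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "rankpurity_model/1",
                   intercept = sprintf("%.17g", model$intercept),
                   n_features = length(model$weights),
                   metadata = model$metadata)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  wt <- data.frame(
    gene_id = names(model$weights),
    weight = sprintf("%.17g", model$weights),
    median_rank = sprintf("%.17g", model$feature_medians[names(model$weights)]),
    mean_correlation = sprintf("%.17g",
      model$features$mean_correlation[match(names(model$weights),
                                            model$features$gene_id)]))
  write.table(wt, file.path(path, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(model$universe, file.path(path, "universe.txt"))
  invisible(path)
}

#' @rdname save_purity_model
#' @export
load_purity_model <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  wt <- read.delim(file.path(path, "weights.tsv"), sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character"))
  weights <- setNames(as.numeric(wt$weight), wt$gene_id)
  new_purity_model(
    universe = readLines(file.path(path, "universe.txt")),
    features = feature_set(wt$gene_id,
                           setNames(as.numeric(wt$mean_correlation), wt$gene_id)),
    weights = weights,
    intercept = as.numeric(manifest$intercept),
    feature_medians = setNames(as.numeric(wt$median_rank), wt$gene_id),
    metadata = manifest$metadata)
}
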