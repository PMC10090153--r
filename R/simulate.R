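#' Simulate a multi-cancer-type bulk cohort of cancer/stroma mixtures
#'
#' Generates bulk expression as linear mixtures of a cancer and a stromal
#' reference profile: sample expression is `p * C_g + (1 - p) * S_g` for
#' purity `p`, where `C_g` and `S_g` are group-specific (cancer-type)
#' references built from a shared log-normal baseline. Informative genes
#' carry a fixed cancer-vs-stroma fold change conserved across groups (half
#' up in cancer, half up in stroma); the remaining genes receive independent
#' group-specific log-normal perturbations of both references, acting as
#' confounders with no consistent purity association across types. Purities
#' are Beta-distributed with group-specific means spanning 0.35-0.72,
#' mimicking the imbalance of real cohorts. Measurement noise is
#' multiplicative log-normal by default (expression is positive and
#' heteroscedastic), with additive Gaussian available.
#'
#' @param n_groups number of pseudo cancer types (default 8).
#' @param samples_per_group samples per type (default 200).
#' @param n_genes genes (default 1000).
#' @param n_informative genes with a conserved cancer-vs-stroma offset
#'   (default 60: 30 cancer-up, 30 stroma-up).
#' @param purity_range interval purities are rescaled into (default
#'   `c(0, 1)`, i.e. the raw Beta draws). A degenerate single-point range is
#'   allowed but warned about, as recovery metrics are then undefined.
#' @param noise_sd measurement noise (log-sd of the multiplicative noise, or
#'   sd of the additive noise relative to signal; default 0.1).
#' @param group_effect_sd log-sd of the group-specific perturbation of
#'   non-informative genes (default 0.15, keeping cancer-type effects
#'   subordinate to the conserved cancer-vs-stroma contrast, which is the
#'   operating assumption of pan-cancer purity models).
#' @param informative_fold conserved cancer-vs-stroma fold change of
#'   informative genes (default 2, giving within-type purity-expression
#'   correlations of roughly 0.5-0.8 at the default noise level, the regime
#'   typical of purity-associated genes in bulk tumors; much larger folds
#'   would make the informative genes statistically near-redundant).
#' @param purity_concentration Beta concentration of the within-type purity
#'   distribution (mean * concentration, (1-mean) * concentration shape
#'   parameters); smaller values give a wider purity spread (default 8).
#' @param noise_model `"lognormal"` (default) or `"gaussian"`.
#' @param seed integer seed; the configuration plus seed reproduce the
#'   cohort exactly.
#' @return a `synthetic_cohort` list: `expr` (samples x genes), `true_purity`
#'   (named), `groups` (named), `informative_genes` (data frame `gene_id`,
#'   `sign` with `+1` = cancer-up), `config`.
#' @export
make_cohort <- function(n_groups = 8L, samples_per_group = 200L,
                        n_genes = 1000L, n_informative = 60L,
                        purity_range = c(0, 1), noise_sd = 0.1,
                        group_effect_sd = 0.15, informative_fold = 2,
                        purity_concentration = 8,
                        noise_model = c("lognormal", "gaussian"), seed) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_informative <= n_genes, length(purity_range) == 2,
            purity_range[1] >= 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2])
  if (purity_range[1] == purity_range[2])
    warning("degenerate purity range: all purities equal; recovery metrics undefined")
  config <- list(n_groups = n_groups, samples_per_group = samples_per_group,
                 n_genes = n_genes, n_informative = n_informative,
                 purity_range = purity_range, noise_sd = noise_sd,
                 group_effect_sd = group_effect_sd,
                 informative_fold = informative_fold,
                 purity_concentration = purity_concentration,
                 noise_model = noise_model, seed = seed)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  group_ids <- sprintf("G%02d", seq_len(n_groups))

  baseline <- exp(rnorm(n_genes, log(10), 1))
  info_idx <- sort(sample.int(n_genes, n_informative))
  sign <- rep(c(1, -1), length.out = n_informative)  # +1: up in cancer
  half_lfc <- log(informative_fold) / 2
  offset <- numeric(n_genes)           # log cancer-vs-baseline offset
  offset[info_idx] <- sign * half_lfc

  mean_grid <- if (n_groups == 1) 0.55 else
    seq(0.35, 0.72, length.out = n_groups)
  conc <- purity_concentration

  expr <- matrix(NA_real_, n_groups * samples_per_group, n_genes,
                 dimnames = list(NULL, genes))
  sample_ids <- character(nrow(expr))
  true_purity <- numeric(nrow(expr))
  groups <- character(nrow(expr))
  references <- list()
  row <- 0L
  for (gi in seq_len(n_groups)) {
    eps_c <- rnorm(n_genes, 0, group_effect_sd)
    eps_s <- rnorm(n_genes, 0, group_effect_sd)
    eps_c[info_idx] <- 0
    eps_s[info_idx] <- 0
    C_g <- baseline * exp(offset + eps_c)
    S_g <- baseline * exp(-offset + eps_s)
    references[[group_ids[gi]]] <- list(cancer = setNames(C_g, genes),
                                        stroma = setNames(S_g, genes))
    p_raw <- rbeta(samples_per_group, mean_grid[gi] * conc,
                   (1 - mean_grid[gi]) * conc)
    p <- purity_range[1] + diff(purity_range) * p_raw
    for (si in seq_len(samples_per_group)) {
      row <- row + 1L
      mix <- p[si] * C_g + (1 - p[si]) * S_g
      x <- if (noise_sd == 0) mix
      else if (noise_model == "lognormal") mix * exp(rnorm(n_genes, 0, noise_sd))
      else pmax(0, mix * (1 + rnorm(n_genes, 0, noise_sd)))
      expr[row, ] <- x
      sample_ids[row] <- sprintf("S%04d", row)
      true_purity[row] <- p[si]
      groups[row] <- group_ids[gi]
    }
  }
  rownames(expr) <- sample_ids
  names(true_purity) <- sample_ids
  names(groups) <- sample_ids
  structure(list(expr = expr, true_purity = true_purity, groups = groups,
                 informative_genes = data.frame(gene_id = genes[info_idx],
                                                sign = sign,
                                                stringsAsFactors = FALSE),
                 references = references, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d genes, %d groups, %d informative genes\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$groups)),
              nrow(x$informative_genes)))
  invisible(x)
}

#' Simulate noisy pseudo-genomics purity estimates
#'
#' Emulates a panel of genomics purity callers applied to a cohort: each
#' method reports the true purity plus a method-specific bias and Gaussian
#' noise, clipped to `[0, 1]`. A fraction of entries is corrupted to extreme
#' values (below 0.1 or above 0.98, as real callers fail at the range ends)
#' and a fraction is missing. Corruption positions are recorded in the
#' `"corruptions"` attribute for test assertions.
#'
#' @param cohort a `synthetic_cohort` (provides the true purities).
#' @param n_methods number of pseudo callers (default 4).
#' @param method_noise_sd per-estimate noise sd (default 0.08).
#' @param bias_range method biases are drawn uniformly from this interval
#'   (default `c(-0.05, 0.05)`).
#' @param extreme_corruption_rate fraction of entries replaced by extreme
#'   values (default 0.05).
#' @param missing_rate fraction of entries set missing (default 0.03).
#' @param seed integer seed.
#' @return samples x methods matrix (`NA` = missing) with attribute
#'   `"corruptions"`, a data frame of corrupted positions and values.
#' @export
make_purity_estimates <- function(cohort, n_methods = 4L,
                                  method_noise_sd = 0.08,
                                  bias_range = c(-0.05, 0.05),
                                  extreme_corruption_rate = 0.05,
                                  missing_rate = 0.03, seed) {
  stopifnot(n_methods >= 1)
  p <- cohort$true_purity
  n <- length(p)
  set.seed(seed)
  bias <- runif(n_methods, bias_range[1], bias_range[2])
  est <- matrix(NA_real_, n, n_methods,
                dimnames = list(names(p), sprintf("method%d", seq_len(n_methods))))
  for (m in seq_len(n_methods))
    est[, m] <- clip01(p + bias[m] + rnorm(n, 0, method_noise_sd))

  corrupt <- matrix(runif(n * n_methods) < extreme_corruption_rate, n, n_methods)
  if (any(corrupt)) {
    k <- sum(corrupt)
    lowside <- runif(k) < 0.5
    vals <- ifelse(lowside, runif(k, 0, 0.1), runif(k, 0.98, 1))
    est[corrupt] <- vals
  }
  miss <- matrix(runif(n * n_methods) < missing_rate, n, n_methods)
  est[miss] <- NA
  pos <- which(corrupt & !miss, arr.ind = TRUE)
  attr(est, "corruptions") <- data.frame(
    sample_id = rownames(est)[pos[, 1]],
    method = colnames(est)[pos[, 2]],
    value = est[pos], stringsAsFactors = FALSE)
  est
}

#' Simulate labeled single-cell expression from a cohort's references
#'
#' Malignant cells are drawn around a group's cancer reference profile and
#' non-malignant cells around its stromal reference, with per-cell
#' multiplicative log-normal noise and Bernoulli dropout to zero — the
#' single-cell analog of the bulk mixture model, used to validate that the
#' selected features separate malignant from non-malignant cells.
#'
#' @param cohort a `synthetic_cohort` (gene set and references are reused).
#' @param n_malignant,n_nonmalignant cell counts (at least 50 each; defaults
#'   1500 and 1000).
#' @param dropout_rate per-entry probability of dropout to zero (default
#'   0.6; a rate of 1 yields an all-zero matrix and a warning).
#' @param group which cohort group's references to use (default the first).
#' @param cell_noise_sd log-sd of per-cell noise (default 0.4; single-cell
#'   profiles are noisier than bulk).
#' @param seed integer seed.
#' @return a `synthetic_single_cell` list: `expr` (cells x genes),
#'   `cell_labels` (`"malignant"` / `"non-malignant"`), `config`.
#' @export
make_single_cell <- function(cohort, n_malignant = 1500L,
                             n_nonmalignant = 1000L, dropout_rate = 0.6,
                             group = NULL, cell_noise_sd = 0.4, seed) {
  stopifnot(n_malignant >= 50, n_nonmalignant >= 50,
            dropout_rate >= 0, dropout_rate <= 1)
  if (dropout_rate == 1)
    warning("dropout_rate 1 yields an all-zero matrix")
  cfg <- cohort$config
  group <- group %||% names(cohort$references)[1]
  if (is.numeric(group)) group <- names(cohort$references)[group]
  ref <- cohort$references[[group]]
  if (is.null(ref)) stop(sprintf("unknown cohort group '%s'", group))
  C_g <- ref$cancer
  S_g <- ref$stroma

  set.seed(seed)
  n_cells <- n_malignant + n_nonmalignant
  genes <- colnames(cohort$expr)
  expr <- matrix(0, n_cells, cfg$n_genes,
                 dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))
  labels <- rep(c("malignant", "non-malignant"), c(n_malignant, n_nonmalignant))
  for (i in seq_len(n_cells)) {
    mu <- if (labels[i] == "malignant") C_g else S_g
    x <- mu * exp(rnorm(cfg$n_genes, 0, cell_noise_sd))
    x <- x * (runif(cfg$n_genes) >= dropout_rate)
    expr[i, ] <- x
  }
  structure(list(expr = expr, cell_labels = setNames(labels, rownames(expr)),
                 config = list(n_malignant = n_malignant,
                               n_nonmalignant = n_nonmalignant,
                               dropout_rate = dropout_rate, group = group,
                               cell_noise_sd = cell_noise_sd, seed = seed)),
            class = "synthetic_single_cell")
}
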