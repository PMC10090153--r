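# Shared fixtures, memoised so expensive cohorts are built once per run.

memoise1 <- function(fn) {
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fn()
    cache
  }
}

# Small cohort for unit tests: 4 pseudo cancer types x 60 samples, 150 genes.
small_cohort <- memoise1(function() {
  make_cohort(n_groups = 4L, samples_per_group = 60L, n_genes = 150L,
              n_informative = 16L, seed = 42L)
})

# Mid-size cohort for selection/model tests (spec example scale:
# few informative genes, 4 groups x 150 samples).
planted_cohort <- memoise1(function() {
  make_cohort(n_groups = 4L, samples_per_group = 150L, n_genes = 100L,
              n_informative = 5L, seed = 77L)
})

# Brute-force per-group Pearson r and RMSE with explicit loops (oracle).
brute_force_score <- function(pred, truth, groups) {
  out <- list()
  for (g in sort(unique(groups))) {
    ids <- names(truth)[groups == g]
    p <- unname(pred[ids]); t <- unname(truth[ids]); n <- length(ids)
    mp <- sum(p) / n; mt <- sum(t) / n
    num <- 0; dp <- 0; dt <- 0; se <- 0
    for (i in seq_len(n)) {
      num <- num + (p[i] - mp) * (t[i] - mt)
      dp <- dp + (p[i] - mp)^2
      dt <- dt + (t[i] - mt)^2
      se <- se + (p[i] - t[i])^2
    }
    out[[g]] <- c(r = num / sqrt(dp * dt), rmse = sqrt(se / n))
  }
  out
}

# Exact two-tailed Wilcoxon signed-rank p-value by full 2^n enumeration
# (assumes no zero differences and no tied |differences|).
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  stopifnot(n <= 16, all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  min(1, p)
}
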