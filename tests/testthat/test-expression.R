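test_that("rank-percentile transform reproduces the worked five-gene example", {
  x <- matrix(c(0, 0, 1, 5, 100), nrow = 1,
              dimnames = list("s1", paste0("g", 1:5)))
  rk <- rank_percentile_transform(x, paste0("g", 1:5))
  expect_equal(as.numeric(rk), c(0.2, 0.2, 0.6, 0.8, 1))
  # min-rank ties: the underlying ranks are [1,1,3,4,5]
  expect_equal(as.numeric(rk) * 5, c(1, 1, 3, 4, 5))
})

test_that("ties and monotone maps behave as rank statistics demand", {
  const <- matrix(rep(7, 4), nrow = 1, dimnames = list("s", paste0("g", 1:4)))
  expect_equal(as.numeric(rank_percentile_transform(const, paste0("g", 1:4))),
               rep(0.25, 4))

  a <- matrix(c(1, 5, 100), nrow = 1, dimnames = list("s", paste0("g", 1:3)))
  b <- matrix(log(c(1, 5, 100)), nrow = 1, dimnames = list("s", paste0("g", 1:3)))
  expect_equal(rank_percentile_transform(a, paste0("g", 1:3)),
               rank_percentile_transform(b, paste0("g", 1:3)))
  expect_equal(as.numeric(rank_percentile_transform(a, paste0("g", 1:3))),
               c(1, 2, 3) / 3)
})

test_that("transform is idempotent on percentiles and scale-invariant per sample", {
  set.seed(1)
  expr <- matrix(rexp(20 * 50), 20, 50,
                 dimnames = list(sprintf("s%02d", 1:20), sprintf("g%02d", 1:50)))
  uni <- colnames(expr)
  rk1 <- rank_percentile_transform(expr, uni)
  rk2 <- rank_percentile_transform(rk1, uni)
  expect_equal(rk1, rk2)

  scaled <- expr
  scaled[7, ] <- expr[7, ] * 3.7
  expect_equal(rank_percentile_transform(scaled, uni), rk1)
})

test_that("rank percentiles always lie in (0, 1] and ties at the max stay below 1", {
  for (seed in 1:5) {
    set.seed(seed)
    expr <- matrix(sample(0:10, 15 * 30, replace = TRUE), 15, 30,
                   dimnames = list(sprintf("s%02d", 1:15), sprintf("g%02d", 1:30)))
    rk <- rank_percentile_transform(expr, colnames(expr))
    expect_true(all(rk > 0 & rk <= 1))
    for (i in 1:15) {
      mx <- max(expr[i, ])
      if (sum(expr[i, ] == mx) > 1) expect_true(all(rk[i, expr[i, ] == mx] < 1))
      else expect_equal(unname(rk[i, which.max(expr[i, ])]), 1)
    }
  }
})

test_that("masked entries stay missing and shrink the percentile denominator", {
  x <- matrix(c(1, 2, NA, 4), nrow = 1, dimnames = list("s", paste0("g", 1:4)))
  rk <- rank_percentile_transform(x, paste0("g", 1:4))
  expect_equal(as.numeric(rk), c(1 / 3, 2 / 3, NA, 1))
})

test_that("transform rejects bad inputs", {
  x <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(rank_percentile_transform(x, c("h1", "h2")), "no universe genes")
  neg <- matrix(c(-1, 2, 3, 4), 2, 2,
                dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(rank_percentile_transform(neg, c("g1", "g2")), "negative")
})

test_that("gene filter keeps a gene alive in any group by either criterion", {
  # 3 groups x 4 samples; gene A fails both criteria everywhere, gene B has
  # high variance in one group only, gene C is well expressed everywhere.
  set.seed(3)
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  names(groups) <- sprintf("s%02d", 1:12)
  A <- rep(0.5, 12) + runif(12, 0, 0.01)          # median ~0.5, var ~0
  B <- c(rep(0.4, 8), c(0, 5, 0.1, 4))            # var > 1 in group 3 only
  C <- rep(10, 12)                                 # median above threshold
  expr <- cbind(A = A, B = B, C = C)
  rownames(expr) <- names(groups)
  expect_equal(filter_genes(expr, groups), c("B", "C"))
})

test_that("gene filter matches per-gene brute-force predicate evaluation", {
  for (seed in c(11, 12)) {
    set.seed(seed)
    n <- 60; p <- 80
    expr <- matrix(rexp(n * p, rate = 0.5), n, p,
                   dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:p)))
    groups <- setNames(sample(c("a", "b", "c"), n, replace = TRUE), rownames(expr))
    got <- filter_genes(expr, groups, expr_threshold = 1.2, var_threshold = 2)
    keep <- logical(p)
    for (j in seq_len(p)) {
      for (g in unique(groups)) {
        v <- expr[groups == g, j]
        if (median(v) >= 1.2 || var(v) >= 2) keep[j] <- TRUE
      }
    }
    expect_equal(got, colnames(expr)[keep])
  }
})

test_that("silent genes are filtered out of a half-expressed cohort", {
  set.seed(30)
  n <- 40
  expressed <- matrix(rexp(n * 50, rate = 0.1), n, 50,
                      dimnames = list(sprintf("s%02d", 1:n),
                                      sprintf("expr%02d", 1:50)))
  silent <- matrix(0, n, 50, dimnames = list(NULL, sprintf("silent%02d", 1:50)))
  expr <- cbind(expressed, silent)
  groups <- setNames(rep(c("a", "b"), each = n / 2), rownames(expr))
  expect_equal(filter_genes(expr, groups), colnames(expressed))
})

test_that("stratified split is exhaustive, deterministic and purity-balanced", {
  co <- small_cohort()
  purity <- co$true_purity
  sp <- stratified_split(purity, co$groups, 0.8, seed = 5)
  expect_length(sp$train, round(0.8 * length(purity)))
  expect_setequal(c(sp$train, sp$test), names(purity))
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- stratified_split(purity, co$groups, 0.8, seed = 5)
  expect_identical(sp, sp2)

  big <- make_cohort(n_groups = 2L, samples_per_group = 200L, n_genes = 20L,
                     n_informative = 4L, seed = 9L)
  sp3 <- stratified_split(big$true_purity, big$groups, 0.8, seed = 6)
  for (g in unique(big$groups)) {
    tr <- intersect(sp3$train, names(big$groups)[big$groups == g])
    te <- intersect(sp3$test, names(big$groups)[big$groups == g])
    expect_lt(abs(mean(big$true_purity[tr]) - mean(big$true_purity[te])), 0.05)
  }
})

test_that("tiny groups fall back to a simple random split with a warning", {
  purity <- setNames(runif(5), paste0("s", 1:5))
  groups <- setNames(rep("only", 5), names(purity))
  expect_warning(sp <- stratified_split(purity, groups, 0.6, seed = 1),
                 "simple random split")
  expect_length(sp$train, 3)
})
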