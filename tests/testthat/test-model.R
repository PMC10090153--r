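make_ranks <- function(n, genes, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * length(genes), 0.01, 1), n, length(genes),
              dimnames = list(sprintf("s%03d", seq_len(n)), genes))
  attr(x, "universe") <- genes
  x
}

test_that("OLS training recovers a noiseless affine relationship exactly", {
  rk <- make_ranks(50, paste0("g", 1:5))
  y <- setNames(0.5 * rk[, "g1"] + 0.1, rownames(rk))
  m <- train_purity_model(rk, y, paste0("g", 1:5))
  expect_lt(abs(m$weights[["g1"]] - 0.5), 1e-6)
  expect_lt(abs(m$intercept - 0.1), 1e-6)
  expect_true(all(abs(m$weights[paste0("g", 2:5)]) < 1e-6))
})

test_that("training is invariant to duplicating the training set", {
  rk <- make_ranks(30, paste0("g", 1:3))
  y <- setNames(rankpurity:::clip01(0.4 * rk[, "g1"] + 0.2 * rk[, "g2"] + rnorm(30, 0, 0.02) + 0.1),
                rownames(rk))
  dup <- rbind(rk, rk)
  rownames(dup) <- c(rownames(rk), paste0(rownames(rk), "_b"))
  attr(dup, "universe") <- attr(rk, "universe")
  ydup <- setNames(c(y, y), rownames(dup))
  m1 <- train_purity_model(rk, y, paste0("g", 1:3))
  m2 <- train_purity_model(dup, ydup, paste0("g", 1:3))
  expect_equal(m1$weights, m2$weights, tolerance = 1e-10)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-10)
})

test_that("rank-deficient designs fall back to minimum-norm least squares", {
  rk <- make_ranks(5, paste0("g", 1:10))
  y <- setNames(runif(5), rownames(rk))
  expect_warning(expect_warning(
    m <- train_purity_model(rk, y, paste0("g", 1:10)),
    "fewer samples"), "minimum-norm")
  expect_length(m$weights, 10)
})

test_that("out-of-range raw predictions are clipped to the nearest bound", {
  genes <- c("g1", "g2")
  high <- rankpurity:::new_purity_model(
    universe = genes,
    features = rankpurity:::feature_set(genes, setNames(c(0.5, 0.5), genes)),
    weights = setNames(c(0, 0), genes), intercept = 1.12,
    feature_medians = setNames(c(0.5, 0.5), genes))
  low <- rankpurity:::new_purity_model(
    universe = genes,
    features = rankpurity:::feature_set(genes, setNames(c(0.5, 0.5), genes)),
    weights = setNames(c(0, 0), genes), intercept = -0.03,
    feature_medians = setNames(c(0.5, 0.5), genes))
  expr <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), genes))
  expect_equal(predict(high, expr)$purity, c(1, 1))
  expect_equal(predict(low, expr)$purity, c(0, 0))
})

test_that("absent feature genes are imputed at their training-median percentile", {
  rk <- make_ranks(40, paste0("g", 1:4))
  y <- setNames(rankpurity:::clip01(0.3 * rk[, "g1"] + 0.2 * rk[, "g2"] + 0.2), rownames(rk))
  m <- train_purity_model(rk, y, paste0("g", 1:2))
  expr <- matrix(rexp(3 * 3), 3, 3,
                 dimnames = list(c("x", "y", "z"), c("g1", "g3", "g4")))
  got <- predict(m, expr)
  expect_equal(got$n_imputed_features, rep(1L, 3))
  # manual three-stage computation with the median plugged in for g2
  rk_new <- rank_percentile_transform(expr, m$universe)
  manual <- rankpurity:::clip01(m$intercept + m$weights[["g1"]] * rk_new[, "g1"] +
                     m$weights[["g2"]] * m$feature_medians[["g2"]])
  expect_equal(got$purity, unname(manual))
})

test_that("predictions are invariant to per-sample positive rescaling and always in [0,1]", {
  co <- small_cohort()
  uni <- filter_genes(co$expr, co$groups)
  rk <- rank_percentile_transform(co$expr, uni)
  fs <- select_features(rk, co$true_purity, co$groups, selection_config(seed = 6L))
  m <- train_purity_model(rk, co$true_purity, fs)
  p1 <- predict(m, co$expr)
  p2 <- predict(m, co$expr * 3.7)
  scaled <- sweep(co$expr, 1, runif(nrow(co$expr), 0.5, 20), `*`)
  p3 <- predict(m, scaled)
  expect_identical(p1, p2)
  expect_identical(p1, p3)
  expect_true(all(p1$purity >= 0 & p1$purity <= 1))
})

test_that("the model predicts held-out synthetic samples accurately", {
  co <- small_cohort()
  sp <- stratified_split(co$true_purity, co$groups, 0.8, seed = 7)
  uni <- filter_genes(co$expr[sp$train, ], co$groups[sp$train])
  rk <- rank_percentile_transform(co$expr[sp$train, ], uni)
  fs <- select_features(rk, co$true_purity[sp$train], co$groups[sp$train],
                        selection_config(seed = 8L))
  m <- train_purity_model(rk, co$true_purity[sp$train], fs)
  fit <- predict(m, co$expr[sp$train, ])
  expect_lte(rankpurity:::rmse(setNames(fit$purity, fit$sample_id)[sp$train],
                               co$true_purity[sp$train]), 0.05)
  held <- predict(m, co$expr[sp$test, ])
  expect_gte(cor(setNames(held$purity, held$sample_id)[sp$test],
                 co$true_purity[sp$test]), 0.9)
})

test_that("model serialization round-trips bit-identically", {
  co <- small_cohort()
  uni <- filter_genes(co$expr, co$groups)
  rk <- rank_percentile_transform(co$expr, uni)
  fs <- select_features(rk, co$true_purity, co$groups, selection_config(seed = 6L))
  m <- train_purity_model(rk, co$true_purity, fs)
  dir <- withr::local_tempdir()
  save_purity_model(m, dir)
  m2 <- load_purity_model(dir)
  expect_identical(predict(m, co$expr), predict(m2, co$expr))
})

test_that("per-cancer-type lasso models fit their own group", {
  co <- small_cohort()
  uni <- filter_genes(co$expr, co$groups)
  rk <- rank_percentile_transform(co$expr, uni)
  models <- train_per_group(rk, co$true_purity, co$groups, seed = 9L)
  expect_named(models, sort(unique(co$groups)))
  for (g in names(models)) {
    ids <- names(co$groups)[co$groups == g]
    pred <- predict(models[[g]], co$expr[ids, ])
    expect_lte(rankpurity:::rmse(pred$purity, unname(co$true_purity[ids])), 0.08)
  }
})

test_that("identical groups give identical per-group models", {
  rk <- make_ranks(60, paste0("g", 1:8), seed = 12)
  y <- setNames(rankpurity:::clip01(0.5 * rk[, "g1"] + 0.2 + rnorm(60, 0, 0.03)), rownames(rk))
  two <- rbind(rk, rk)
  rownames(two) <- c(rownames(rk), paste0(rownames(rk), "_b"))
  attr(two, "universe") <- paste0("g", 1:8)
  y2 <- setNames(c(y, y), rownames(two))
  groups <- setNames(rep(c("a", "b"), each = 60), rownames(two))
  models <- train_per_group(two, y2, groups, seed = 3L)
  expect_equal(models$a$weights, models$b$weights)
  expect_equal(models$a$intercept, models$b$intercept)
})

test_that("a pure-noise group collapses to a near-constant model at its mean label", {
  set.seed(23)
  rk <- make_ranks(80, paste0("g", 1:30), seed = 31)
  y <- setNames(runif(80, 0.3, 0.7), rownames(rk))  # unrelated to features
  groups <- setNames(rep("noise", 80), rownames(rk))
  models <- train_per_group(rk, y, groups, seed = 13L)
  pred <- predict(models$noise, matrix(rexp(80 * 30), 80, 30,
                                       dimnames = dimnames(rk)))
  expect_lt(sd(pred$purity), 0.05)
  expect_lt(abs(mean(pred$purity) - mean(y)), 0.05)
})

test_that("leave-one-group-out trains each model without its target group", {
  co <- small_cohort()
  uni <- filter_genes(co$expr, co$groups)
  rk <- rank_percentile_transform(co$expr, uni)
  fs <- select_features(rk, co$true_purity, co$groups, selection_config(seed = 6L))
  two <- names(co$groups)[co$groups %in% c("G01", "G02")]
  sub <- rk[two, ]
  attr(sub, "universe") <- attr(rk, "universe")
  models <- train_leave_one_group_out(sub, co$true_purity[two],
                                      co$groups[two], fs)
  expect_named(models, c("G01", "G02"))
  expect_equal(models$G01$metadata$withheld_group, "G01")
  expect_false(isTRUE(all.equal(models$G01$weights, models$G02$weights)))
  expect_error(train_leave_one_group_out(rk[co$groups == "G01", ],
                                         co$true_purity[co$groups == "G01"],
                                         co$groups[co$groups == "G01"], fs),
               ">= 2")
})
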