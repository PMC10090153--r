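# internal helpers shared across modules

# clip to [0,1]; keeps names/dim (pmin/pmax would drop them)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder apportionment of `total` draws across strata with
# capacities `cap`, proportional to capacity. Never exceeds a capacity.
allocate_proportional <- function(cap, total) {
  stopifnot(total <= sum(cap))
  quota <- cap / sum(cap) * total
  take <- pmin(floor(quota), cap)
  while (sum(take) < total) {
    room <- which(take < cap)
    frac <- (quota - take)[room]
    pick <- room[which.max(frac)]
    take[pick] <- take[pick] + 1L
  }
  take
}

# Split values into up to n_strata near-equal bins by ascending rank.
# Used for purity-decile stratification.
rank_strata <- function(x, n_strata = 10L) {
  n <- length(x)
  k <- min(n_strata, n)
  as.integer(ceiling(rank(x, ties.method = "first") / (n / k)))
}

# Validate a samples x genes (or cells x genes) expression matrix.
check_expression <- function(expr, allow_na = FALSE, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(sprintf("`%s` must be a numeric matrix (samples in rows, genes in columns)", arg))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop(sprintf("`%s` must have sample row names and gene column names", arg))
  if (anyDuplicated(rownames(expr))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate gene identifiers")
  vals <- expr[!is.na(expr)]
  if (!allow_na && anyNA(expr)) stop(sprintf("`%s` contains missing values", arg))
  if (any(!is.finite(vals))) stop(sprintf("`%s` contains non-finite values", arg))
  if (any(vals < 0)) stop(sprintf("`%s` contains negative values; linear-scale expression expected", arg))
  invisible(expr)
}

# Align a per-sample annotation vector (groups, purity) with the rows of a
# matrix; accepts a named vector or one in matching order.
align_samples <- function(x, sample_ids, arg = "x") {
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing) > 0)
      stop(sprintf("`%s` is missing %d sample(s), e.g. %s", arg,
                   length(missing), missing[1]))
    x <- x[sample_ids]
  } else {
    if (length(x) != length(sample_ids))
      stop(sprintf("`%s` must be named or have one entry per sample", arg))
    names(x) <- sample_ids
  }
  x
}

strip_ws <- function(x) trimws(as.character(x))
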