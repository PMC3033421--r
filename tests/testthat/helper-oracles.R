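# Independent brute-force oracles used across test files.  These deliberately
# avoid the package's own code paths.

# Overall regression F via lm(), the reference for all F-statistic tests.
oracle_overall_f <- function(y, S) {
  fit <- stats::lm(y ~ ., data = as.data.frame(S))
  unname(summary(fit)$fstatistic[1])
}

oracle_ols_r2 <- function(y, X) {
  summary(stats::lm(y ~ ., data = as.data.frame(X)))$r.squared
}

# Pooled-permutation FDR by a literal double loop over genes and permutations.
oracle_pooled_fdr_raw <- function(observed, permuted) {
  g <- length(observed)
  total <- length(permuted)
  sapply(seq_len(g), function(m) {
    exceed_null <- 0
    for (i in seq_len(nrow(permuted)))
      for (j in seq_len(ncol(permuted)))
        if (permuted[i, j] >= observed[m]) exceed_null <- exceed_null + 1
    exceed_obs <- sum(observed >= observed[m])
    (exceed_null / total) / (exceed_obs / g)
  })
}

# Exhaustive tagSNP search: best worst-case r^2 coverage over all subsets.
oracle_best_tag_coverage <- function(X, n_tags) {
  r2 <- cor(X)^2
  subsets <- utils::combn(ncol(X), n_tags)
  best <- -Inf
  for (i in seq_len(ncol(subsets))) {
    cov <- apply(r2[, subsets[, i], drop = FALSE], 1, max)
    best <- max(best, min(cov))
  }
  best
}

# Coverage objective of a given tag set (same definition as the oracle above).
tag_coverage <- function(X, tags) {
  r2 <- cor(X)^2
  min(apply(r2[, tags, drop = FALSE], 1, max))
}

# A genotype matrix of three independent blocks of perfectly correlated SNPs.
three_block_geno <- function(n = 60, seed = 42) {
  set.seed(seed)
  base <- sapply(1:3, function(i) rbinom(n, 2, 0.4))
  # ensure polymorphism in every block
  base[1, ] <- 0; base[2, ] <- 2
  g <- cbind(base[, 1], base[, 1], base[, 2], base[, 2], base[, 3], base[, 3])
  genotype_matrix(g)
}

# Fixed small region spec used by several files.
toy_spec <- function(k = 6, maf = 0.3, dprime = 0.8, causal = integer(0)) {
  region_spec(k = k, maf = maf, dprime = dprime, causal = causal)
}
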