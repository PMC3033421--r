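set.seed(40)
GENO <- simulate_genotypes(toy_spec(k = 6, maf = 0.3, dprime = 0.7), 150)
Y <- rnorm(150) + 0.4 * unclass(GENO)[, 3]

test_that("PLS statistic with one component is the squared score t-statistic", {
  fit <- fit_pls(GENO, Y, m = 1)
  u <- drop(component_scores(fit, 1))
  tstat <- summary(stats::lm(Y ~ u))$coefficients["u", "t value"]
  expect_equal(pls_mlas_stat(GENO, Y, m = 1), tstat^2,
               tolerance = 1e-10, ignore_attr = TRUE)
  # and matches the lm overall F oracle
  expect_equal(pls_mlas_stat(GENO, Y, m = 1), oracle_overall_f(Y, u),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the fast permutation closure agrees with the reference statistic", {
  fn <- plsmlas:::build_stat_fn(GENO, "PLS_MLAS", m = 1)
  expect_equal(fn(GENO, Y), pls_mlas_stat(GENO, Y, 1),
               tolerance = 1e-10, ignore_attr = TRUE)
  for (mth in c("PCA_MLAS", "FTSM", "WTSM")) {
    fn <- plsmlas:::build_stat_fn(GENO, mth, m = 1)
    ref <- switch(mth,
                  PCA_MLAS = pca_mlas_stat(GENO, Y, 1),
                  FTSM = tsm(single_locus_pvalues(GENO, Y, "F")),
                  WTSM = tsm(single_locus_pvalues(GENO, Y, "Wald")))
    expect_equal(fn(GENO, Y), ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("PCA statistic uses variance-ordered components and the eigen oracle", {
  X <- unclass(GENO)[, 1:6]
  Xc <- sweep(X, 2, colMeans(X))
  S <- plsmlas:::pca_scores(X, 3)
  v <- apply(S, 2, var)
  expect_true(all(diff(v) <= 1e-9))
  # PC1 from brute-force eigendecomposition, within sign
  ev <- eigen(crossprod(Xc))$vectors[, 1]
  pc1 <- drop(Xc %*% ev)
  agree <- min(sum((S[, 1] - pc1)^2), sum((S[, 1] + pc1)^2))
  expect_lt(agree, 1e-8 * sum(pc1^2))
  # single column: PCA and PLS statistics coincide
  x1 <- unclass(GENO)[, 1, drop = FALSE]
  expect_equal(pca_mlas_stat(x1, Y, 1), pls_mlas_stat(x1, Y, 1),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("greedy tagSNP selection handles its canonical cases", {
  g3 <- three_block_geno()
  # three perfect-LD blocks, three tags: one per block, optimal coverage
  tags <- select_tagsnps(g3, 3)
  blocks <- c(1, 1, 2, 2, 3, 3)
  expect_equal(sort(unique(blocks[tags])), 1:3)
  expect_equal(tag_coverage(unclass(g3), tags),
               oracle_best_tag_coverage(unclass(g3), 3))
  # all SNPs mutually r^2 = 1: ties broken by lowest index
  x <- rbinom(40, 2, 0.4); x[1] <- 0; x[2] <- 2
  gsame <- genotype_matrix(cbind(x, x, x, x))
  expect_equal(select_tagsnps(gsame, 2), c(1L, 2L))
  # n_tags = k returns all polymorphic SNPs
  expect_equal(select_tagsnps(g3, 6), 1:6)
})

test_that("tagSNP statistic equals the OLS overall F on the tag columns", {
  tags <- select_tagsnps(GENO, 3)
  expect_equal(tagsnp_mlas_stat(GENO, Y, tags),
               oracle_overall_f(Y, unclass(GENO)[, tags]),
               tolerance = 1e-10, ignore_attr = TRUE)
  # one tag: squared t of the simple regression
  t1 <- summary(stats::lm(Y ~ unclass(GENO)[, 2]))$coefficients[2, "t value"]
  expect_equal(tagsnp_mlas_stat(GENO, Y, 2L), t1^2,
               tolerance = 1e-10, ignore_attr = TRUE)
  # duplicated (collinear) tags reduce to the full-rank subset
  gdup <- genotype_matrix(cbind(unclass(GENO)[, 1:2], unclass(GENO)[, 2]))
  expect_equal(tagsnp_mlas_stat(gdup, Y, 1:3),
               oracle_overall_f(Y, unclass(GENO)[, 1:2]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("tail strength measure matches hand-evaluated cases", {
  k <- 7
  expect_equal(tsm((1:k) / (k + 1)), 0, tolerance = 1e-12)
  expect_equal(tsm(c(0.1, 0.2, 0.3)), 0.6, tolerance = 1e-12)
  expect_equal(tsm(rev(c(0.1, 0.2, 0.3))), 0.6, tolerance = 1e-12)  # order-free
  expect_equal(tsm(rep(0, 5)), 1)
  expect_error(tsm(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(tsm(numeric(0)), "at least one")
})

test_that("single-locus p-values match the lm oracle and handle edge cases", {
  p_f <- single_locus_pvalues(GENO, Y, "F")
  p_lm <- apply(unclass(GENO), 2, function(x)
    summary(stats::lm(Y ~ x))$coefficients[2, "Pr(>|t|)"])
  expect_equal(p_f, unname(p_lm), tolerance = 1e-10)
  # Wald is anti-conservative relative to F in small samples, converges at
  # large n
  set.seed(41)
  gbig <- simulate_genotypes(toy_spec(k = 4, maf = 0.3, dprime = 0.5), 5000)
  ybig <- rnorm(5000) + 0.05 * unclass(gbig)[, 1]
  dF <- single_locus_pvalues(gbig, ybig, "F")
  dW <- single_locus_pvalues(gbig, ybig, "Wald")
  expect_true(all(abs(dF - dW) < 0.005))
  # monomorphic SNP carries no information
  gm <- genotype_matrix(cbind(unclass(GENO)[, 1], 0L))
  expect_equal(single_locus_pvalues(gm, Y)[2], 1)
})

test_that("all statistics are invariant to allele-coding flips", {
  flip <- unclass(GENO)
  flip[, c(2, 5)] <- 2L - flip[, c(2, 5)]
  gf <- genotype_matrix(flip)
  expect_equal(pls_mlas_stat(gf, Y, 1), pls_mlas_stat(GENO, Y, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(pca_mlas_stat(gf, Y, 1), pca_mlas_stat(GENO, Y, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tsm(single_locus_pvalues(gf, Y, "F")),
               tsm(single_locus_pvalues(GENO, Y, "F")), tolerance = 1e-9)
  expect_equal(select_tagsnps(gf, 3), select_tagsnps(GENO, 3))
})

test_that("empirical p-values are invariant to trait location and scale", {
  for (mth in c("PLS_MLAS", "PCA_MLAS", "TAGSNP_MLAS", "FTSM")) {
    r1 <- mlas_test(GENO, Y, mth, B = 50, seed = 42)
    r2 <- mlas_test(GENO, 3 * Y + 7, mth, B = 50, seed = 42)
    expect_equal(r1$empirical_p, r2$empirical_p)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  }
})

test_that("a perfect linear fit attains the permutation floor", {
  fit <- fit_pls(GENO, Y, m = 1)
  y_perfect <- drop(component_scores(fit, 1)) * 2 + 1
  out <- mlas_test(GENO, y_perfect, "PLS_MLAS", B = 99, seed = 43)
  expect_equal(out$empirical_p, 1 / 100)
})
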