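test_that("benchmark grid carries the canonical epistatic settings", {
  g <- benchmark_grid("epistatic")
  expect_length(g, 4)
  expect_equal(g[[1]]$dprime_band, c(0.9, 1.0))
  expect_equal(g[[1]]$additive_vars, c("6" = 0.020, "10" = 0.010))
  expect_equal(g[[1]]$interaction_var, 0)
  expect_equal(g[[4]]$additive_vars, c("6" = 0.014, "10" = 0.004))
  expect_equal(g[[4]]$interaction_var, 0.012)
  ga <- benchmark_grid("additive")
  expect_true(all(vapply(ga, function(r) names(r$additive_vars), "") == "8"))
  expect_true(all(vapply(ga, function(r) r$interaction_var, 0) == 0))
})

test_that("derive_seed is deterministic, distinct and in range", {
  s <- vapply(0:500, function(i) derive_seed(123, i), integer(1))
  expect_equal(anyDuplicated(s), 0L)
  expect_true(all(s >= 1 & s <= 2^31 - 1))
  expect_identical(derive_seed(123, 42), derive_seed(123, 42))
  expect_false(derive_seed(124, 42) == derive_seed(123, 42))
})

test_that("run_replicate excludes causal columns and is reproducible", {
  set_epi <- benchmark_grid("epistatic")[[1]]
  p1 <- run_replicate(set_epi, "epistatic", c("PLS_MLAS", "FTSM"),
                      seed = 99, n = 120, B = 30)
  p2 <- run_replicate(set_epi, "epistatic", c("PLS_MLAS", "FTSM"),
                      seed = 99, n = 120, B = 30)
  expect_identical(p1, p2)
  expect_named(p1, c("PLS_MLAS", "FTSM"))
  expect_true(all(p1 >= 1 / 31 & p1 <= 1))

  # the analyzed matrix drops the causal columns: 12 under epistatic,
  # 13 under additive (observable through the region width used by tagging)
  expect_equal(length(plsmlas:::causal_indices("epistatic")), 2L)
  expect_equal(length(plsmlas:::causal_indices("additive")), 1L)
  set.seed(99)
  spec <- random_region_spec(14, set_epi$dprime_band, causal = c(6L, 10L))
  g <- simulate_genotypes(spec, 120)
  expect_equal(n_snps(g[, -c(6, 10)]), 12L)
})

test_that("estimate_power is deterministic and detects a planted effect", {
  strong <- list(dprime_band = c(0.9, 1.0),
                 additive_vars = c("8" = 0.08), interaction_var = 0,
                 label = "strong")
  null_row <- list(dprime_band = c(0.9, 1.0),
                   additive_vars = c("8" = 0), interaction_var = 0,
                   label = "null")
  design <- study_design("additive", settings = list(null_row, strong),
                         R = 40, n = 150, B = 60, methods = "PLS_MLAS",
                         seed = 5)
  res <- estimate_power(design)
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$estimate >= 0 & res$estimate <= 1))
  expect_equal(res$se, sqrt(res$estimate * (1 - res$estimate) / 40))
  # power under a strong effect clearly exceeds the null rejection rate
  expect_gt(res$estimate[res$setting == "strong"],
            res$estimate[res$setting == "null"])
  expect_identical(res, estimate_power(design))
})

test_that("genome_scan recovers planted genes and validates inputs", {
  set.seed(60)
  n <- 150; n_genes <- 8; k_gene <- 3
  mats <- list(); regions <- list()
  for (g in seq_len(n_genes)) {
    spec <- toy_spec(k = k_gene, maf = 0.3, dprime = 0.6)
    gm <- simulate_genotypes(spec, n)
    colnames(gm) <- paste0("g", g, "_s", seq_len(k_gene))
    mats[[g]] <- unclass(gm)
    regions[[paste0("gene", g)]] <- colnames(gm)
  }
  geno <- genotype_matrix(do.call(cbind, mats))
  # plant a strong effect in gene 3
  y <- rnorm(n) + 0.8 * unclass(geno)[, "g3_s2"]
  res <- genome_scan(geno, y, regions, B = 99, seed = 2)
  expect_equal(res$gene, paste0("gene", 1:n_genes))
  expect_equal(res$n_snps, rep(k_gene, n_genes))
  expect_equal(which.max(res$statistic), 3L)
  expect_equal(which.min(res$q), 3L)
  expect_true(all(res$q >= 0 & res$q <= 1))
  ord <- order(res$statistic)
  expect_true(all(diff(res$q[ord]) <= 1e-12))
  # single-gene scan: observed-proportion denominator is 1
  res1 <- genome_scan(geno, y, regions["gene3"], B = 99, seed = 2)
  expect_equal(nrow(res1), 1L)

  expect_warning(genome_scan(geno, y, c(regions, list(ghost = "nope")),
                             B = 20, seed = 1), "no matched SNPs")
  expect_error(genome_scan(geno, rnorm(10), regions, B = 20), "mismatch")
})

test_that("a permuted-trait scan stays null", {
  set.seed(61)
  n <- 120
  geno <- simulate_genotypes(toy_spec(k = 12, maf = 0.3, dprime = 0.7), n)
  regions <- split(colnames(geno), rep(1:4, each = 3))
  names(regions) <- paste0("gene", 1:4)
  y <- rnorm(n)  # no genetic signal at all
  res <- genome_scan(geno, y, regions, B = 199, seed = 3)
  expect_true(all(res$p >= 0.005))
  expect_gt(min(res$q), 0)
})
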