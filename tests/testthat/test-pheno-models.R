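test_that("epistatic indicator fires only on (2,2), (2,1), (1,2)", {
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  got <- epistatic_indicator(grid$g1, grid$g2)
  want <- as.integer(paste(grid$g1, grid$g2) %in% c("2 2", "2 1", "1 2"))
  expect_equal(got, want)
  expect_error(epistatic_indicator(3, 1), "dosages")
})

test_that("effect_config enforces its invariants", {
  expect_error(effect_config("additive", c("8" = 1.2)), "< 1")
  expect_error(effect_config("additive", c("8" = 0.1), interaction_var = 0.1),
               "no interaction")
  expect_error(effect_config("epistatic", c("6" = 0.02), 0.01, c(6, 10)),
               "two causal")
  expect_error(effect_config("epistatic", c("6" = 0.02, "10" = 0.01), 0.01),
               "interaction_pair")
  cfg <- effect_config("additive", c("8" = 0.02))
  expect_equal(cfg$resid_sd, sqrt(0.98))
})

test_that("calibration converts variance fractions to coefficients", {
  spec <- region_spec(k = 3, maf = 0.25, dprime = 0.5)
  cfg0 <- effect_config("additive", c("2" = 0))
  expect_equal(unname(calibrate_effects(cfg0, spec)$beta), 0)

  cfg <- effect_config("additive", c("2" = 0.01))
  eff <- calibrate_effects(cfg, spec)
  expect_equal(unname(eff$beta), sqrt(0.01 / (2 * 0.25 * 0.75)),
               tolerance = 1e-12)  # ~0.1633
  expect_equal(unname(eff$beta), 0.1633, tolerance = 1e-4)
})

test_that("simulated traits hit their variance-fraction targets", {
  # additive: realized fraction of Var(Y) from the causal SNP
  spec <- region_spec(k = 3, maf = 0.25, dprime = 0.5)
  cfg <- effect_config("additive", c("2" = 0.01))
  set.seed(21)
  g <- simulate_genotypes(spec, 2e5)
  y <- simulate_trait(g, cfg, spec, seed = 22)
  eff <- calibrate_effects(cfg, spec)
  frac <- var(eff$beta * unclass(g)[, 2]) / var(y)
  expect_lt(abs(frac - 0.01), 0.0015)
  # squared correlation between trait and causal dosage ~ target fraction
  expect_lt(abs(cor(y, unclass(g)[, 2])^2 - 0.01), 0.002)
})

test_that("degenerate trait models behave exactly", {
  spec <- region_spec(k = 2, maf = 0.3, dprime = 0)
  set.seed(23)
  g <- simulate_genotypes(spec, 500)
  # all effects zero: pure N(0,1) noise
  y0 <- simulate_trait(g, effect_config("additive", c("1" = 0)), spec,
                       seed = 24)
  expect_equal(sd(y0), 1, tolerance = 0.1)
  # trait decomposes exactly into calibrated genetic part + N(0, sigma) noise
  cfg1 <- effect_config("additive", c("1" = 0.3))
  eff1 <- calibrate_effects(cfg1, spec)
  y1 <- simulate_trait(g, cfg1, spec, seed = 25)
  resid <- y1 - unclass(g)[, 1] * eff1$beta
  expect_equal(sd(resid), eff1$sigma, tolerance = 0.1)
  # bit-identical rerun under the same seed
  expect_identical(y1, simulate_trait(g, cfg1, spec, seed = 25))
})

test_that("epistatic generator with zero interaction equals additive", {
  spec <- region_spec(k = 14, maf = 0.3, dprime = 0.9, causal = c(6L, 10L))
  set.seed(26)
  g <- simulate_genotypes(spec, 300)
  av <- c("6" = 0.02, "10" = 0.01)
  y_epi <- simulate_trait(g, effect_config("epistatic", av, 0, c(6, 10)),
                          spec, seed = 27)
  y_add <- simulate_trait(g, effect_config("additive", av), spec, seed = 27)
  expect_identical(y_epi, y_add)
})

test_that("epistatic interaction variance is calibrated through the LD chain", {
  set.seed(28)
  spec <- region_spec(k = 14, maf = runif(14, 0.2, 0.5), dprime = 0.95,
                      causal = c(6L, 10L))
  cfg <- effect_config("epistatic", c("6" = 0.016, "10" = 0.006), 0.008,
                       c(6, 10))
  g <- simulate_genotypes(spec, 2e5)
  eff <- calibrate_effects(cfg, spec)
  ind <- epistatic_indicator(unclass(g)[, 6], unclass(g)[, 10])
  y <- simulate_trait(g, cfg, spec, seed = 29)
  expect_lt(abs(var(eff$gamma * ind) / var(y) - 0.008), 0.002)
})
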