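#' Deterministic per-replicate seed derivation
#'
#' Every replicate of a study draws its own seed from the root seed and a
#' counter via a fixed integer mix (`(root + index * 2654435761) mod
#' (2^31 - 1) + 1`, exact in double arithmetic for the index ranges used), so
#' any single replicate can be re-run in isolation.
#'
#' @param root integer root seed.
#' @param index non-negative replicate counter.
#' @return Integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) %% 2147483647 +
              as.numeric(index) * 2654435761) %% 2147483647) + 1L
}

#' The benchmark parameter grid
#'
#' Rows of the simulation study design: adjacent-pair D-prime band plus the
#' variance fractions of the causal effects.  The epistatic model places
#' additive effects at SNPs 6 and 10 of a 14-SNP region and one interaction
#' between them; the additive model places a single additive effect at SNP 8.
#' The epistatic basic configuration is D' 0.9-1.0 with fractions
#' (0.020, 0.010, 0.000).
#'
#' @param model `"epistatic"` or `"additive"`.
#' @return List of setting rows; each has `dprime_band`, `additive_vars`,
#'   `interaction_var`, `label`.
#' @export
benchmark_grid <- function(model = c("epistatic", "additive")) {
  model <- match.arg(model)
  if (model == "epistatic") {
    rows <- list(
      list(dprime_band = c(0.9, 1.0), v = c(0.020, 0.010), vint = 0.000),
      list(dprime_band = c(0.8, 0.9), v = c(0.018, 0.008), vint = 0.004),
      list(dprime_band = c(0.7, 0.8), v = c(0.016, 0.006), vint = 0.008),
      list(dprime_band = c(0.6, 0.7), v = c(0.014, 0.004), vint = 0.012))
    lapply(rows, function(r)
      list(dprime_band = r$dprime_band,
           additive_vars = c("6" = r$v[1], "10" = r$v[2]),
           interaction_var = r$vint,
           label = sprintf("D'%.1f-%.1f v6=%.3f v10=%.3f vint=%.3f",
                           r$dprime_band[1], r$dprime_band[2],
                           r$v[1], r$v[2], r$vint)))
  } else {
    # additive arm: genetic-effect sweep at tight LD plus a D' sweep at a
    # fixed middling effect
    effects <- c(0.005, 0.010, 0.015, 0.020)
    rows <- c(
      lapply(effects, function(v)
        list(dprime_band = c(0.9, 1.0), v = v)),
      lapply(list(c(0.8, 0.9), c(0.7, 0.8), c(0.6, 0.7)), function(b)
        list(dprime_band = b, v = 0.010)))
    lapply(rows, function(r)
      list(dprime_band = r$dprime_band,
           additive_vars = c("8" = r$v),
           interaction_var = 0,
           label = sprintf("D'%.1f-%.1f v8=%.3f",
                           r$dprime_band[1], r$dprime_band[2], r$v)))
  }
}

#' Simulation study design
#'
#' @param model `"epistatic"` or `"additive"` trait-generating model.
#' @param settings list of setting rows as produced by [benchmark_grid()]
#'   (default: the full grid for `model`).
#' @param R replicates per setting (benchmark scale 5000; desk default 1000).
#' @param n subjects per replicate (default 800).
#' @param B permutations per test (benchmark scale 2000; desk default 200).
#' @param alpha nominal significance level for power counting (0.05).
#' @param methods method labels from [mlas_methods()].
#' @param k SNPs per region (14).
#' @param n_tags tagSNPs for the tagSNP comparator (3).
#' @param seed root seed.
#' @return A `study_design` list.
#' @export
study_design <- function(model = c("epistatic", "additive"),
                         settings = NULL, R = 1000L, n = 800L, B = 200L,
                         alpha = 0.05, methods = mlas_methods(), k = 14L,
                         n_tags = 3L, seed = 1L) {
  model <- match.arg(model)
  if (is.null(settings)) settings <- benchmark_grid(model)
  methods <- match.arg(methods, mlas_methods(), several.ok = TRUE)
  stopifnot(R >= 1L, n >= 10L, B >= 1L, alpha > 0, alpha < 1)
  structure(list(model = model, settings = settings, R = as.integer(R),
                 n = as.integer(n), B = as.integer(B), alpha = alpha,
                 methods = methods, k = as.integer(k),
                 n_tags = as.integer(n_tags), seed = as.integer(seed)),
            class = "study_design")
}

# Causal SNP positions: 6 and 10 (epistatic) or 8 (additive) in a 14-SNP
# region, scaled proportionally for other region widths.
causal_indices <- function(model, k = 14L) {
  k <- as.integer(k)
  if (model == "epistatic") {
    c1 <- max(1L, as.integer(round(k * 6 / 14)))
    c2 <- min(k, max(c1 + 1L, as.integer(round(k * 10 / 14))))
    c(c1, c2)
  } else {
    max(1L, min(k, as.integer(round(k * 8 / 14))))
  }
}

#' Run one benchmark replicate
#'
#' Simulates one region (MAFs uniform on `[0.2, 0.5]`, adjacent D-prime
#' uniform in the setting's band) and its trait, removes the causal SNP
#' columns from the analyzed matrix (leaving 12 columns under the epistatic
#' model, 13 under the additive), and runs each requested method's
#' permutation test.
#'
#' @param setting one row of [benchmark_grid()].
#' @param model `"epistatic"` or `"additive"`.
#' @param methods method labels.
#' @param seed integer seed for this replicate.
#' @param n subjects.
#' @param B permutations.
#' @param k SNPs per region.
#' @param n_tags tagSNPs.
#' @return Named numeric vector of empirical p-values, one per method.
#' @export
run_replicate <- function(setting, model, methods, seed, n = 800L, B = 200L,
                          k = 14L, n_tags = 3L) {
  set.seed(seed)
  causal <- causal_indices(model, k)
  spec <- random_region_spec(k = k, dprime_band = setting$dprime_band,
                             causal = causal)
  geno <- simulate_genotypes(spec, n)
  av <- setting$additive_vars
  names(av) <- as.character(causal[seq_along(av)])
  cfg <- effect_config(model = model,
                       additive_vars = av,
                       interaction_var = setting$interaction_var,
                       interaction_pair = if (model == "epistatic") causal)
  y <- simulate_trait(geno, cfg, spec)
  analyzed <- genotype_matrix(geno_as_matrix(geno)[, -causal, drop = FALSE])
  vapply(methods, function(mth)
    mlas_test(analyzed, y, mth, B = B, n_tags = n_tags)$empirical_p,
    numeric(1))
}

#' Estimate power / type-I error over a study design
#'
#' For each setting x method, the proportion of replicates whose permutation
#' p-value is at or below the nominal level; under all-zero effect fractions
#' this proportion is the type-I error.  Fully deterministic given the root
#' seed: replicate r of setting s uses `derive_seed(seed, (s - 1) * 10^5 + r)`.
#'
#' @param design a [study_design()].
#' @param verbose print per-setting progress to stderr.
#' @return A data frame (class `study_result`) with columns `setting`,
#'   `method`, `estimate`, `se` (binomial, `sqrt(p(1-p)/R)`), `R`.
#' @export
estimate_power <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  out <- list()
  for (s in seq_along(design$settings)) {
    setting <- design$settings[[s]]
    pmat <- matrix(NA_real_, design$R, length(design$methods),
                   dimnames = list(NULL, design$methods))
    for (r in seq_len(design$R)) {
      pmat[r, ] <- run_replicate(setting, design$model, design$methods,
                                 seed = derive_seed(design$seed,
                                                    (s - 1) * 1e5 + r),
                                 n = design$n, B = design$B, k = design$k,
                                 n_tags = design$n_tags)
    }
    est <- colMeans(pmat <= design$alpha)
    out[[s]] <- data.frame(setting = setting$label,
                           method = design$methods,
                           estimate = unname(est),
                           se = unname(sqrt(est * (1 - est) / design$R)),
                           R = design$R, row.names = NULL)
    if (verbose)
      message(sprintf("[%d/%d] %s: %s", s, length(design$settings),
                      setting$label,
                      paste(sprintf("%s=%.3f", design$methods, est),
                            collapse = " ")))
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_result", class(res))
  res
}
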