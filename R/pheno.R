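#' Trait-generating model configuration
#'
#' Describes how a quantitative trait is generated from causal SNP dosages:
#' additive per-SNP effects, optionally one pairwise epistatic effect, each
#' specified as the fraction of total phenotypic variance it should explain.
#' Total phenotypic variance is normalized to 1, so the residual standard
#' deviation is `sqrt(1 - sum of fractions)`; the association tests are
#' location/scale invariant, making the normalization inconsequential.
#'
#' @param model `"additive"` or `"epistatic"`.
#' @param additive_vars named numeric vector: names are causal SNP column
#'   indices, values the target fractions of phenotypic variance explained by
#'   each SNP's additive effect (e.g. `c("8" = 0.02)`).
#' @param interaction_var fraction of variance explained by the epistatic
#'   indicator term (0 under the additive model).
#' @param interaction_pair length-2 integer vector naming the interacting SNP
#'   columns (required when `interaction_var` is used; the epistatic model
#'   requires exactly two causal SNPs and this one pair).
#' @param intercept trait intercept (default 0; tests are location invariant).
#' @return An object of class `effect_config`.
#' @examples
#' effect_config("epistatic", c("6" = 0.02, "10" = 0.01), 0.004, c(6, 10))
#' @export
effect_config <- function(model = c("additive", "epistatic"),
                          additive_vars = numeric(0),
                          interaction_var = 0,
                          interaction_pair = NULL,
                          intercept = 0) {
  model <- match.arg(model)
  additive_vars <- unlist(additive_vars)
  if (length(additive_vars) && is.null(names(additive_vars)))
    stop("'additive_vars' must be named by causal SNP column index")
  if (any(additive_vars < 0) || interaction_var < 0)
    stop("variance fractions must be non-negative")
  total <- sum(additive_vars) + interaction_var
  if (total >= 1) stop("variance fractions must sum to < 1")
  if (model == "additive" && interaction_var > 0)
    stop("the additive model has no interaction term")
  if (model == "epistatic") {
    if (length(additive_vars) != 2L)
      stop("the epistatic model names exactly two causal SNPs")
    if (is.null(interaction_pair) || length(interaction_pair) != 2L)
      stop("the epistatic model requires one 'interaction_pair'")
    interaction_pair <- as.integer(interaction_pair)
  }
  structure(list(model = model,
                 additive_vars = additive_vars,
                 interaction_var = interaction_var,
                 interaction_pair = interaction_pair,
                 intercept = intercept,
                 resid_sd = sqrt(1 - total)),
            class = "effect_config")
}

#' Epistatic high-risk genotype indicator
#'
#' For a pair of causal SNPs, a subject is "jointly at risk" when the two
#' dosages are (2,2), (2,1) or (1,2): at least one allele of each SNP and both
#' alleles of one of them.
#'
#' @param g_j,g_u dosage vectors (0/1/2), recycled to a common length.
#' @return Integer 0/1 vector.
#' @examples
#' epistatic_indicator(c(2, 1, 0), c(1, 1, 2))  # 1, 0, 0
#' @export
epistatic_indicator <- function(g_j, g_u) {
  if (!all(g_j %in% c(0, 1, 2)) || !all(g_u %in% c(0, 1, 2)))
    stop("dosages must be 0, 1 or 2")
  as.integer((g_j == 2L & g_u >= 1L) | (g_j == 1L & g_u == 2L))
}

# Joint distribution of the minor-allele indicator at two (possibly
# non-adjacent) loci under the Markov haplotype chain: the chain's transition
# matrices between the loci are multiplied out.
haplotype_joint_dist <- function(spec, j, u) {
  stopifnot(j < u, u <= spec$k)
  trans <- diag(2)  # rows: allele at j (minor, major); cols: allele at u
  for (s in j:(u - 1L)) {
    f <- pair_haplotype_freqs(spec$maf[s], spec$maf[s + 1L], spec$dprime[s])
    step <- f / rowSums(f)
    trans <- trans %*% step
  }
  p_j <- c(spec$maf[j], 1 - spec$maf[j])
  joint <- trans * p_j  # P(h_j = a, h_u = b), row a in (minor, major)
  joint
}

# P(g_j = a, g_u = b) for a,b in 0..2 under HWE pairing of two independent
# haplotypes, each with the joint two-locus law above.
genotype_joint_dist <- function(spec, j, u) {
  hj <- haplotype_joint_dist(spec, j, u)
  # haplotype states: 1 = (minor,minor), 2 = (minor,major), 3 = (major,minor),
  # 4 = (major,major); dosage contribution of state s at (j, u):
  add_j <- c(1L, 1L, 0L, 0L)
  add_u <- c(1L, 0L, 1L, 0L)
  p <- c(hj[1, 1], hj[1, 2], hj[2, 1], hj[2, 2])
  out <- matrix(0, 3, 3, dimnames = list(g_j = 0:2, g_u = 0:2))
  for (s1 in 1:4) for (s2 in 1:4) {
    a <- add_j[s1] + add_j[s2]
    b <- add_u[s1] + add_u[s2]
    out[a + 1L, b + 1L] <- out[a + 1L, b + 1L] + p[s1] * p[s2]
  }
  out
}

#' Convert variance-explained targets into regression coefficients
#'
#' Under Hardy-Weinberg equilibrium a dosage with minor-allele frequency `p`
#' has variance `2p(1 - p)`, so an additive effect explaining a fraction `v`
#' of unit total phenotypic variance needs coefficient
#' `beta = sqrt(v / (2p(1 - p)))`.  The epistatic coefficient uses the exact
#' Bernoulli variance of the high-risk indicator, computed analytically from
#' the joint genotype distribution of the two causal SNPs implied by the
#' haplotype chain (their LD included).
#'
#' @param config an [effect_config()].
#' @param spec the [region_spec()] the genotypes are simulated from (supplies
#'   MAFs and, for the epistatic term, the LD path between the causal pair).
#' @return List with `beta` (named numeric, per causal SNP), `gamma` (scalar),
#'   `sigma` (residual SD) and `alpha` (intercept).
#' @export
calibrate_effects <- function(config, spec) {
  stopifnot(inherits(config, "effect_config"), inherits(spec, "region_spec"))
  idx <- as.integer(names(config$additive_vars))
  if (length(idx) && (any(idx < 1L) || any(idx > spec$k)))
    stop("causal SNP indices outside the region")
  p <- spec$maf[idx]
  g_var <- 2 * p * (1 - p)
  if (any(config$additive_vars > 0 & g_var <= 0))
    stop("cannot target nonzero variance with a zero-variance predictor")
  beta <- sqrt(config$additive_vars / g_var)
  names(beta) <- names(config$additive_vars)
  gamma <- 0
  if (config$interaction_var > 0) {
    pr <- sort(config$interaction_pair)
    jd <- genotype_joint_dist(spec, pr[1], pr[2])
    p_ind <- jd[3, 3] + jd[3, 2] + jd[2, 3]  # (2,2), (2,1), (1,2)
    v_ind <- p_ind * (1 - p_ind)
    if (v_ind <= 0) stop("epistatic indicator has zero variance")
    gamma <- sqrt(config$interaction_var / v_ind)
  }
  list(beta = beta, gamma = gamma, sigma = config$resid_sd,
       alpha = config$intercept)
}

#' Simulate a quantitative trait from genotypes
#'
#' `Y_i = alpha + sum_j beta_j X_ij + gamma * I(epistatic risk) + e_i` with
#' `e_i ~ N(0, sigma^2)` i.i.d.  Coefficients come from [calibrate_effects()]
#' so each term explains its configured fraction of phenotypic variance.
#'
#' @param geno a [genotype_matrix()].
#' @param config an [effect_config()].
#' @param spec the [region_spec()] used to simulate `geno` (for calibration).
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   trait is reproducible in isolation.
#' @return Numeric trait vector of length `n_subjects(geno)`.
#' @export
simulate_trait <- function(geno, config, spec, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  eff <- calibrate_effects(config, spec)
  idx <- as.integer(names(eff$beta))
  if (length(idx) && max(idx) > n_snps(geno))
    stop("causal SNP index exceeds genotype columns")
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects(geno)
  g <- geno_as_matrix(geno)
  y <- rep(eff$alpha, n)
  if (length(idx)) y <- y + drop(g[, idx, drop = FALSE] %*% eff$beta)
  if (eff$gamma != 0) {
    pr <- config$interaction_pair
    y <- y + eff$gamma * epistatic_indicator(g[, pr[1]], g[, pr[2]])
  }
  y + rnorm(n, 0, eff$sigma)
}

#' @export
print.effect_config <- function(x, ...) {
  cat("effect_config (", x$model, "): additive fractions {",
      paste(sprintf("%s: %.3f", names(x$additive_vars), x$additive_vars),
            collapse = ", "),
      "}, interaction ", format(x$interaction_var),
      ", residual sd ", sprintf("%.4f", x$resid_sd), "\n", sep = "")
  invisible(x)
}
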