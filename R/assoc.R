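#' Association test statistics for candidate genetic regions
#'
#' Five multilocus statistics are available, all reducing the region to a
#' small regression so that degrees of freedom stay low:
#' \describe{
#'   \item{PLS_MLAS}{overall F of the trait regressed on the top-m PLS scores.}
#'   \item{PCA_MLAS}{overall F on the top-m principal-component scores of the
#'     centered genotype matrix (eigen-ordered by variance).}
#'   \item{TAGSNP_MLAS}{overall F on a greedy r-squared tagSNP subset; under
#'     the global null of the 1-df interaction model the interaction term
#'     vanishes, so the main-effects F is the null test.}
#'   \item{FTSM / WTSM}{tail strength measure over per-SNP F-test or Wald-test
#'     p-values.}
#' }
#' All are assessed by trait permutation (see [permute_and_test()]); none has
#' a usable closed-form null at region-scale k.
#'
#' @name assoc-statistics
NULL

# Overall F for H0: all slopes 0 in y ~ 1 + S.  Rank-deficient S is reduced
# to a full-rank column subset via pivoted QR; perfect fits give a large
# finite statistic so permutation ranking stays well-defined.
overall_f_stat <- function(y, S) {
  n <- length(y)
  S <- as.matrix(S)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss == 0 || ncol(S) == 0L) return(0)
  Sc <- sweep(S, 2L, colMeans(S))
  qrS <- qr(Sc)
  r <- qrS$rank
  if (r == 0L) return(0)
  fitted <- qr.fitted(qrS, yc)
  rss <- sum((yc - fitted)^2)
  ess <- tss - rss
  df2 <- n - r - 1L
  if (df2 <= 0L) return(0)
  stat <- (ess / r) / max(rss / df2, tss * 1e-300)
  attr(stat, "df") <- c(r, df2)
  stat
}

#' PLS-based multilocus statistic
#'
#' Overall regression F statistic for the trait on the top-`m` PLS component
#' scores (intercept included).  A degenerate fit (trait orthogonal to the
#' genotypes, zero components) returns 0, the most null-like value.
#'
#' @param geno [genotype_matrix()] or plain dosage matrix.
#' @param y numeric trait vector.
#' @param m number of PLS components (default 1, the benchmark setting).
#' @return F statistic (finite; `df` attached as an attribute).
#' @export
pls_mlas_stat <- function(geno, y, m = 1L) {
  fit <- fit_pls(geno, y, m = m)
  if (fit$n_components == 0L) return(0)
  overall_f_stat(y, component_scores(fit, min(m, fit$n_components)))
}

#' PCA-based multilocus statistic
#'
#' As [pls_mlas_stat()] but the predictors are the top-`m` principal-component
#' scores of the centered genotype matrix, ordered by eigenvalue.  PCA ignores
#' the trait, so the components capture genotype variance only.
#'
#' @inheritParams pls_mlas_stat
#' @return F statistic.
#' @export
pca_mlas_stat <- function(geno, y, m = 1L) {
  S <- pca_scores(geno, m)
  if (is.null(S)) return(0)
  overall_f_stat(y, S)
}

pca_scores <- function(geno, m) {
  X <- if (inherits(geno, "genotype_matrix")) geno_as_matrix(geno) else as.matrix(geno)
  storage.mode(X) <- "double"
  Xc <- sweep(X, 2L, colMeans(X))
  if (sum(Xc^2) == 0) return(NULL)
  sv <- svd(Xc, nu = min(m, min(dim(Xc))), nv = 0)
  pos <- sv$d[seq_len(ncol(sv$u))] > 1e-12 * sv$d[1]
  if (!any(pos)) return(NULL)
  sweep(sv$u[, pos, drop = FALSE], 2L, sv$d[which(pos)], "*")
}

#' Greedy r-squared tagSNP selection
#'
#' Picks `n_tags` SNPs maximizing the worst-case coverage
#' `min_j max_{t in tags} r^2(j, t)` over polymorphic SNPs, greedily: at each
#' step the SNP giving the largest coverage objective is added, ties broken by
#' lowest column index.  Deterministic; monomorphic columns are excluded from
#' candidacy (and from the coverage objective, which they cannot attain).
#'
#' @param geno [genotype_matrix()] or dosage matrix.
#' @param n_tags number of tags wanted (capped at the number of polymorphic
#'   SNPs).
#' @return Integer vector of selected column indices, in increasing order.
#' @export
select_tagsnps <- function(geno, n_tags) {
  X <- if (inherits(geno, "genotype_matrix")) geno_as_matrix(geno) else as.matrix(geno)
  storage.mode(X) <- "double"
  n_tags <- as.integer(n_tags)
  if (n_tags < 1L) stop("'n_tags' must be >= 1")
  poly <- which(apply(X, 2L, stats::sd) > 0)
  if (!length(poly)) stop("no polymorphic SNPs to tag")
  n_tags <- min(n_tags, length(poly))
  r2 <- suppressWarnings(cor(X[, poly, drop = FALSE]))^2
  r2[!is.finite(r2)] <- 0
  p <- length(poly)
  covered <- rep(0, p)   # best r2 to any selected tag, per polymorphic SNP
  tags <- integer(0)
  for (step in seq_len(n_tags)) {
    best <- -Inf; best_c <- NA_integer_
    for (c in seq_len(p)) {
      if (c %in% tags) next
      obj <- min(pmax(covered, r2[, c]))
      if (obj > best + 1e-12) { best <- obj; best_c <- c }
    }
    tags <- c(tags, best_c)
    covered <- pmax(covered, r2[, best_c])
  }
  unname(sort(poly[tags]))
}

#' TagSNP-based multilocus statistic
#'
#' Overall F statistic testing the global null (no main effect at any tag) of
#' the 1-df interaction regression restricted to the tag SNPs.  Under that
#' null the interaction parameter multiplies a product of null main effects
#' and drops out, so the test is the overall main-effects F on the tag
#' columns.  Collinear tags are reduced to a full-rank subset (pivoted QR).
#'
#' @param geno [genotype_matrix()] or dosage matrix.
#' @param y trait vector.
#' @param tags integer column indices from [select_tagsnps()].
#' @return F statistic.
#' @export
tagsnp_mlas_stat <- function(geno, y, tags) {
  X <- if (inherits(geno, "genotype_matrix")) geno_as_matrix(geno) else as.matrix(geno)
  if (!length(tags)) stop("'tags' must name at least one SNP column")
  overall_f_stat(y, X[, tags, drop = FALSE])
}

#' Tail strength measure
#'
#' For k p-values with ascending order statistics `p_(1) <= ... <= p_(k)`,
#' `TSM = (1/k) sum_i [1 - p_(i) * (k + 1) / i]`.  Under the global null each
#' `p_(i)` has expectation `i / (k + 1)`, so TSM has expectation 0; an excess
#' of small p-values pushes TSM positive.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (any order).
#' @return TSM statistic (at most 1, attained when all p-values are 0).
#' @examples
#' tsm(c(0.1, 0.2, 0.3))  # 0.6
#' @export
tsm <- function(p_values) {
  p <- as.numeric(p_values)
  k <- length(p)
  if (k < 1L) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  ps <- sort(p)
  mean(1 - ps * (k + 1) / seq_len(k))
}

#' Per-SNP single-locus p-values
#'
#' Simple linear regression of the trait on each SNP dosage.  The `"F"`
#' variant reports the regression F-test p-value (df 1 and n-2); the
#' `"Wald"` variant reports the two-sided asymptotic-normal p-value of
#' `beta_hat / SE(beta_hat)`, matching the additive quantitative-trait Wald
#' test of standard GWAS software.  Monomorphic SNPs carry no information and
#' get p = 1.
#'
#' @param geno [genotype_matrix()] or dosage matrix.
#' @param y trait vector (length `nrow(geno)`, n >= 3).
#' @param test `"F"` or `"Wald"`.
#' @return Numeric vector of k p-values.
#' @export
single_locus_pvalues <- function(geno, y, test = c("F", "Wald")) {
  test <- match.arg(test)
  X <- if (inherits(geno, "genotype_matrix")) geno_as_matrix(geno) else as.matrix(geno)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(geno)")
  if (n < 3L) stop("need at least 3 subjects")
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  ssx <- colSums(Xc^2)
  ssy <- sum(yc^2)
  p <- rep(1, ncol(X))
  ok <- ssx > 0 & ssy > 0
  if (any(ok)) {
    num <- drop(crossprod(Xc[, ok, drop = FALSE], yc))
    r2 <- pmin(num^2 / (ssx[ok] * ssy), 1 - 1e-15)
    fstat <- (n - 2) * r2 / (1 - r2)
    p[ok] <- if (test == "F") pf(fstat, 1, n - 2, lower.tail = FALSE)
             else 2 * pnorm(-sqrt(fstat))
  }
  p
}

# Fast closure factory used by permutation loops: precomputes everything that
# depends on the genotypes only, so each permuted trait costs a few small
# matrix products.  Methods: PLS_MLAS, PCA_MLAS, TAGSNP_MLAS, FTSM, WTSM.
build_stat_fn <- function(geno, method, m = 1L, n_tags = 3L) {
  X <- if (inherits(geno, "genotype_matrix")) geno_as_matrix(geno) else as.matrix(geno)
  storage.mode(X) <- "double"
  n <- nrow(X)
  poly <- which(apply(X, 2L, stats::sd) > 0)
  Xc <- sweep(X[, poly, drop = FALSE], 2L, colMeans(X[, poly, drop = FALSE]))
  switch(method,
    PLS_MLAS = {
      if (m == 1L) {
        xnorm <- sqrt(sum(Xc^2))
        function(geno_ignored, y) {
          yc <- y - mean(y)
          s <- drop(crossprod(Xc, yc))
          ns2 <- sum(s^2)
          yy <- sum(yc^2)
          if (ns2 <= (1e-12 * xnorm * sqrt(yy))^2 || yy == 0) return(0)
          u <- drop(Xc %*% s)          # unnormalized score, scale-free below
          uu <- sum(u^2)
          if (uu == 0) return(0)
          r2 <- min(ns2^2 / (uu * yy), 1 - 1e-15)
          (n - 2) * r2 / (1 - r2)
        }
      } else {
        function(geno_ignored, y) pls_mlas_stat(Xc, y, m = m)
      }
    },
    PCA_MLAS = {
      S <- pca_scores(Xc, m)
      function(geno_ignored, y) {
        if (is.null(S)) return(0)
        overall_f_stat(y, S)
      }
    },
    TAGSNP_MLAS = {
      tags <- select_tagsnps(X, n_tags)
      Xt <- X[, tags, drop = FALSE]
      function(geno_ignored, y) overall_f_stat(y, Xt)
    },
    FTSM = ,
    WTSM = {
      test <- if (method == "FTSM") "F" else "Wald"
      ssx <- colSums(Xc^2)
      k_all <- ncol(X)
      function(geno_ignored, y) {
        yc <- y - mean(y)
        ssy <- sum(yc^2)
        p <- rep(1, k_all)
        if (ssy > 0 && length(poly)) {
          num <- drop(crossprod(Xc, yc))
          r2 <- pmin(num^2 / (ssx * ssy), 1 - 1e-15)
          fstat <- (n - 2) * r2 / (1 - r2)
          p[poly] <- if (test == "F") pf(fstat, 1, n - 2, lower.tail = FALSE)
                     else 2 * pnorm(-sqrt(fstat))
        }
        tsm(p)
      }
    },
    stop("unknown method: ", method)
  )
}

#' Available multilocus test method labels
#' @return Character vector of method names accepted by [mlas_test()].
#' @export
mlas_methods <- function() c("PLS_MLAS", "PCA_MLAS", "TAGSNP_MLAS", "FTSM", "WTSM")
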