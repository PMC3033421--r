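#' Fit partial least-squares components of genotypes against a trait
#'
#' Iterative univariate-response PLS (NIPALS-type with deflation).  At step j
#' the weight vector is the normalized cross-product
#' `w_j = X_j' y_j / ||X_j' y_j||` — for a univariate response this *is* the
#' first left singular vector of the cross-product matrix, so no iterative
#' SVD is needed.  Scores, loadings and deflation follow
#' `u_j = X_j w_j`, `a_j = u_j' y_j / u_j' u_j`, `b_j = X_j' u_j / u_j' u_j`,
#' `X_{j+1} = X_j - u_j b_j'`, `y_{j+1} = y_j - a_j u_j`.
#'
#' Columns of `X` and `y` are mean-centered before extraction; genotype
#' columns share the dosage scale, so no unit-variance scaling is applied
#' (set `scale = TRUE` to standardize).  Extraction stops early with a
#' warning flag when the residual trait is numerically orthogonal to the
#' residual genotypes (`||X_j' y_j||` below `1e-12 * ||X_j||_F ||y_j||`) or
#' when the genotype rank is exhausted, returning the components found.
#'
#' @param X numeric genotype matrix (or [genotype_matrix()]), subjects in rows.
#' @param y numeric trait vector.
#' @param m maximum number of components (capped at `min(n - 1, k)`).
#' @param center center `X` columns and `y` (default TRUE; disable only if
#'   inputs are pre-centered).
#' @param scale scale `X` columns to unit variance (default FALSE).
#' @return An object of class `pls_model`: `weights` (k x m), `scores`
#'   (n x m, the `u_j`), `y_loadings` (length m `a_j`), `x_loadings` (k x m
#'   `b_j`), `variance_explained` (per-component fraction of the total
#'   centered genotype variance), `n_components`, and `early_stop` flag.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200, 2, 0.3), 50, 4)
#' y <- X[, 2] * 0.5 + rnorm(50)
#' fit <- fit_pls(X, y, m = 2)
#' head(component_scores(fit, 1))
#' @export
fit_pls <- function(X, y, m = 1L, center = TRUE, scale = FALSE) {
  if (inherits(X, "genotype_matrix")) X <- geno_as_matrix(X)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  m <- min(m, n - 1L, k)
  if (center) {
    X <- sweep(X, 2L, colMeans(X))
    y <- y - mean(y)
  }
  if (scale) {
    s <- apply(X, 2L, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2L, s, "/")
  }
  total_var <- sum(X^2)

  W <- matrix(0, k, m); U <- matrix(0, n, m); Bl <- matrix(0, k, m)
  a <- numeric(m); vexp <- numeric(m)
  Xj <- X; yj <- y
  found <- 0L; early <- FALSE
  for (j in seq_len(m)) {
    s_j <- drop(crossprod(Xj, yj))
    ns <- sqrt(sum(s_j^2))
    tol <- 1e-12 * sqrt(sum(Xj^2)) * sqrt(sum(yj^2))
    if (!is.finite(ns) || ns <= tol) { early <- TRUE; break }
    w <- s_j / ns
    u <- drop(Xj %*% w)
    uu <- sum(u^2)
    if (uu <= 1e-12 * sum(Xj^2) / max(k, 1L)) { early <- TRUE; break }
    aj <- sum(u * yj) / uu
    bj <- drop(crossprod(Xj, u)) / uu
    W[, j] <- w; U[, j] <- u; a[j] <- aj; Bl[, j] <- bj
    vexp[j] <- if (total_var > 0) uu * sum(bj^2) / total_var else 0
    Xj <- Xj - tcrossprod(u, bj)
    yj <- yj - aj * u
    found <- j
  }
  keep <- seq_len(found)
  structure(list(weights = W[, keep, drop = FALSE],
                 scores = U[, keep, drop = FALSE],
                 y_loadings = a[keep],
                 x_loadings = Bl[, keep, drop = FALSE],
                 variance_explained = vexp[keep],
                 n_components = found,
                 early_stop = early,
                 n = n, k = k),
            class = "pls_model")
}

#' Score matrix of the leading PLS components
#'
#' @param model a [fit_pls()] result.
#' @param top_m number of leading components wanted.
#' @return `n x top_m` matrix whose columns are the score vectors
#'   `u_1, ..., u_top_m` in extraction order.
#' @export
component_scores <- function(model, top_m = model$n_components) {
  stopifnot(inherits(model, "pls_model"))
  top_m <- as.integer(top_m)
  if (top_m < 0L || top_m > model$n_components)
    stop("'top_m' exceeds the number of extracted components")
  model$scores[, seq_len(top_m), drop = FALSE]
}

#' Number of components needed to reach a genotype-variance threshold
#'
#' Smallest `m` whose components jointly explain at least `threshold` of the
#' total (centered) genotype variance; always at least 1.  Intended for the
#' genome-scan mode; the simulation benchmark fixes one component.
#'
#' @param model a [fit_pls()] result.
#' @param threshold fraction in (0, 1].
#' @return Integer component count.
#' @export
select_m_by_variance <- function(model, threshold = 0.8) {
  stopifnot(inherits(model, "pls_model"))
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  if (model$n_components == 0L) return(0L)
  cum <- cumsum(model$variance_explained)
  hit <- which(cum >= threshold - 1e-15)
  if (length(hit)) max(1L, hit[1L]) else model$n_components
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$n_components, "component(s) on", x$n, "subjects x",
      x$k, "SNPs\n")
  if (x$n_components)
    cat("genotype variance explained:",
        paste(sprintf("%.3f", x$variance_explained), collapse = ", "), "\n")
  if (x$early_stop) cat("(extraction stopped early: rank/signal exhausted)\n")
  invisible(x)
}
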