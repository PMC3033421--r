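#' Permutation plan
#'
#' Bundles the permutation count, RNG seed and the statistic to evaluate.
#'
#' @param statistic_fn function of `(geno, y)` returning a scalar statistic
#'   (larger = more association).
#' @param B number of permutations (>= 1).
#' @param seed optional integer seed; with a seed, [permute_and_test()] is
#'   bit-reproducible.
#' @param label method label stored in the outcome.
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(statistic_fn, B = 2000L, seed = NULL,
                             label = "custom") {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be a positive integer")
  stopifnot(is.function(statistic_fn))
  structure(list(statistic_fn = statistic_fn, B = B, seed = seed,
                 label = label),
            class = "permutation_plan")
}

#' Add-one empirical p-value
#'
#' `p = (1 + #\{b : permuted_b >= observed\}) / (B + 1)`.  Ties count as
#' exceedances (inclusive `>=`), and the observed statistic is counted as one
#' of its own permutation draws, so `p` is a strictly valid permutation
#' p-value in `[1/(B+1), 1]`.
#'
#' @param observed observed statistic.
#' @param permuted numeric vector of B permutation statistics.
#' @return Empirical p-value.
#' @examples
#' empirical_p(5, rep(1, 99))  # 0.01
#' @export
empirical_p <- function(observed, permuted) {
  if (!is.finite(observed)) stop("'observed' must be finite")
  B <- length(permuted)
  if (B < 1L) stop("need at least one permutation statistic")
  (1 + sum(permuted >= observed)) / (B + 1)
}

#' Permutation test of a region statistic
#'
#' Evaluates the plan's statistic on the observed trait, then on `B` uniform
#' random permutations of the trait (genotype rows fixed — equivalent to
#' permuting genotype rows, and deterministic given the seed).  Statistics
#' that depend on the trait, such as PLS components, are recomputed from
#' scratch against each permuted trait.  A statistic failure on a permutation
#' is logged and scored 0 (the most null-like value).
#'
#' @param geno [genotype_matrix()] or dosage matrix.
#' @param y trait vector.
#' @param plan a [permutation_plan()].
#' @param return_permuted keep the permutation statistics in the result
#'   (needed for pooled FDR across genes).
#' @return A `test_outcome`: list with `method`, `statistic`, `B`,
#'   `empirical_p`, and optionally `permuted`.
#' @export
permute_and_test <- function(geno, y, plan, return_permuted = FALSE) {
  stopifnot(inherits(plan, "permutation_plan"))
  y <- as.numeric(y)
  if (!is.null(plan$seed)) set.seed(plan$seed)
  observed <- as.numeric(plan$statistic_fn(geno, y))[1]
  if (!is.finite(observed)) observed <- 0
  n <- length(y)
  permuted <- numeric(plan$B)
  for (b in seq_len(plan$B)) {
    yp <- y[sample.int(n)]
    st <- tryCatch(as.numeric(plan$statistic_fn(geno, yp))[1],
                   error = function(e) {
                     warning("permutation ", b, " failed: ",
                             conditionMessage(e), call. = FALSE)
                     0
                   })
    permuted[b] <- if (is.finite(st)) st else 0
  }
  out <- list(method = plan$label, statistic = observed, B = plan$B,
              empirical_p = empirical_p(observed, permuted))
  if (return_permuted) out$permuted <- permuted
  structure(out, class = "test_outcome")
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", empirical p = ", format(x$empirical_p, digits = 4),
      " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' One region, one method, permutation inference
#'
#' High-level wrapper joining the statistic factories to the permutation
#' machinery: builds the requested method's statistic on this region and
#' returns its permutation test outcome.
#'
#' @param geno [genotype_matrix()] or dosage matrix.
#' @param y trait vector.
#' @param method one of [mlas_methods()].
#' @param B permutation count.
#' @param seed optional integer seed.
#' @param m PLS/PCA component count (default 1).
#' @param n_tags tagSNP count for `TAGSNP_MLAS` (default 3).
#' @param return_permuted keep the permutation statistics.
#' @return A `test_outcome`.
#' @examples
#' spec <- region_spec(k = 6, maf = 0.3, dprime = 0.8)
#' set.seed(7)
#' g <- simulate_genotypes(spec, 120)
#' y <- rnorm(120)
#' mlas_test(g, y, "PLS_MLAS", B = 99, seed = 1)
#' @export
mlas_test <- function(geno, y, method = "PLS_MLAS", B = 2000L, seed = NULL,
                      m = 1L, n_tags = 3L, return_permuted = FALSE) {
  method <- match.arg(method, mlas_methods())
  fn <- build_stat_fn(geno, method, m = m, n_tags = n_tags)
  plan <- permutation_plan(fn, B = B, seed = seed, label = method)
  permute_and_test(geno, y, plan, return_permuted = return_permuted)
}

#' Pooled-permutation FDR q-values
#'
#' For gene-level statistics `T_m` and a genes x B matrix of permutation
#' statistics, the raw q-value of gene m is the ratio of two exceedance
#' proportions at threshold `T_m`: the proportion of *all* pooled permutation
#' statistics at or above `T_m` (an estimate of the expected null discovery
#' fraction) over the proportion of observed statistics at or above `T_m`
#' (the realized discovery fraction).  Both proportions use inclusive `>=`.
#' Raw ratios are clipped to `[0, 1]` and monotonized by a running minimum in
#' decreasing significance (each gene receives the smallest clipped q among
#' genes with statistics at or below its own), so q is monotone
#' non-increasing in T.
#'
#' @param observed numeric vector of per-gene observed statistics.
#' @param permuted numeric matrix, `length(observed)` rows x B columns, row
#'   order matching `observed`.
#' @return Data frame with `statistic`, `q_raw` (the raw ratio, unclipped)
#'   and `q` (clipped then monotonized), rows in the input gene order.
#' @export
pooled_fdr <- function(observed, permuted) {
  observed <- as.numeric(observed)
  if (!length(observed)) stop("'observed' must be non-empty")
  permuted <- as.matrix(permuted)
  if (nrow(permuted) != length(observed))
    stop("'permuted' must have one row per observed statistic")
  if (!ncol(permuted)) stop("'permuted' must have at least one column")
  pool <- as.numeric(permuted)
  q_raw <- vapply(observed, function(t) {
    null_prop <- mean(pool >= t)
    obs_prop <- mean(observed >= t)   # >= 1/g, includes the gene itself
    null_prop / obs_prop
  }, numeric(1))
  q_clip <- pmin(pmax(q_raw, 0), 1)
  # q(T) = min clipped q over genes with statistic <= T: monotone
  # non-increasing in T, tie-consistent
  ord <- order(observed)
  ts <- observed[ord]
  cm <- cummin(q_clip[ord])
  q_mon <- numeric(length(observed))
  q_mon[ord] <- cm[findInterval(ts, ts)]
  data.frame(statistic = observed, q_raw = q_raw, q = q_mon)
}
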