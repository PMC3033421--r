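#' Specification of a simulated genetic region
#'
#' A region is a run of `k` consecutive SNPs characterized by per-SNP
#' minor-allele frequencies (MAF) and the D-prime linkage-disequilibrium
#' coefficient between each adjacent pair.  Haplotypes are generated as a
#' first-order Markov chain over the SNPs, so only adjacent-pair LD is
#' controlled directly; LD between non-adjacent SNPs is whatever the chain
#' induces (roughly the product of the adjacent correlations).
#'
#' @param k number of SNPs (>= 2).
#' @param maf numeric vector of length `k` (or length 1, recycled) of
#'   minor-allele frequency targets, each in `[0.2, 0.5]`.
#' @param dprime numeric vector of length `k - 1` (or length 1, recycled) of
#'   adjacent-pair D-prime targets, each in `[0, 1]`.
#' @param causal integer vector of 1-based causal SNP indices (may be empty).
#'
#' @return An object of class `region_spec` with fields `k`, `maf`, `dprime`,
#'   `causal`.
#' @examples
#' region_spec(k = 3, maf = c(0.2, 0.3, 0.4), dprime = 0.9)
#' @export
region_spec <- function(k = 14L, maf = 0.3, dprime = 0.9, causal = integer(0)) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2")
  maf <- rep_len(as.numeric(maf), k)
  dprime <- rep_len(as.numeric(dprime), k - 1L)
  if (any(!is.finite(maf)) || any(maf < 0.2 - 1e-12) || any(maf > 0.5 + 1e-12))
    stop("all 'maf' must lie in [0.2, 0.5]")
  if (any(!is.finite(dprime)) || any(dprime < 0) || any(dprime > 1))
    stop("all 'dprime' must lie in [0, 1]")
  causal <- as.integer(causal)
  if (length(causal) && (any(causal < 1L) || any(causal > k)))
    stop("'causal' indices must lie in 1..k")
  structure(list(k = k, maf = maf, dprime = dprime, causal = causal),
            class = "region_spec")
}

#' Draw a random region specification
#'
#' Emulates picking one region at random from a large pool of real genetic
#' regions: MAFs are drawn uniformly on `[0.2, 0.5]` and every adjacent-pair
#' D-prime uniformly within `dprime_band`.  Drawing a fresh spec per
#' replicate is distributionally equivalent to sampling with replacement from
#' an arbitrarily large pre-built pool.
#'
#' @param k number of SNPs.
#' @param dprime_band length-2 numeric, lower and upper D-prime bounds.
#' @param causal causal SNP indices, passed through to [region_spec()].
#' @return A `region_spec`.
#' @export
random_region_spec <- function(k = 14L, dprime_band = c(0.9, 1.0),
                               causal = integer(0)) {
  stopifnot(length(dprime_band) == 2L, dprime_band[1] <= dprime_band[2])
  region_spec(k = k,
              maf = runif(k, 0.2, 0.5),
              dprime = runif(as.integer(k) - 1L, dprime_band[1], dprime_band[2]),
              causal = causal)
}

#' @export
print.region_spec <- function(x, ...) {
  cat("region_spec: ", x$k, " SNPs; MAF [",
      sprintf("%.3f", min(x$maf)), ", ", sprintf("%.3f", max(x$maf)),
      "]; adjacent D' [", sprintf("%.3f", min(x$dprime)), ", ",
      sprintf("%.3f", max(x$dprime)), "]", sep = "")
  if (length(x$causal)) cat("; causal:", paste(x$causal, collapse = ","))
  cat("\n")
  invisible(x)
}
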