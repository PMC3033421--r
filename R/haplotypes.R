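#' Two-locus haplotype frequencies at a target D-prime
#'
#' Builds the 2x2 haplotype frequency table for two biallelic SNPs with minor
#' allele frequencies `p1`, `p2` and normalized LD coefficient D' = `dprime`.
#' The raw coefficient is `D = dprime * Dmax` with
#' `Dmax = min(p1 * (1 - p2), (1 - p1) * p2)`; coupling is always positive
#' (minor alleles co-occur), which is immaterial for coding-symmetric tests.
#'
#' @param p1,p2 minor-allele frequencies, each in (0, 1).
#' @param dprime target D' in `[0, 1]`.
#' @return A 2x2 numeric matrix of haplotype frequencies; rows index the first
#'   SNP's allele (`minor`, `major`), columns the second's.  Entries are
#'   non-negative and sum to 1, with marginals `p1` and `p2`.
#' @examples
#' pair_haplotype_freqs(0.3, 0.3, 0)    # independence: f(minor,minor) = 0.09
#' pair_haplotype_freqs(0.3, 0.3, 1)    # complete LD: one haplotype absent
#' @export
pair_haplotype_freqs <- function(p1, p2, dprime) {
  if (!is.finite(p1) || !is.finite(p2) || p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("'p1' and 'p2' must lie strictly in (0, 1)")
  if (!is.finite(dprime) || dprime < 0 || dprime > 1)
    stop("'dprime' must lie in [0, 1]")
  d_max <- min(p1 * (1 - p2), (1 - p1) * p2)
  d <- dprime * d_max
  f <- matrix(c(p1 * p2 + d,       p1 * (1 - p2) - d,
                (1 - p1) * p2 - d, (1 - p1) * (1 - p2) + d),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("minor", "major"), c("minor", "major")))
  # numerical guard: D <= Dmax by construction, clamp round-off only
  f[f < 0 & f > -1e-15] <- 0
  f
}

#' Estimate D-prime from a two-locus haplotype frequency table
#'
#' Inverse of [pair_haplotype_freqs()]: recovers `|D| / Dmax` from observed
#' haplotype frequencies (rows = first SNP minor/major, columns = second).
#'
#' @param f 2x2 frequency (or count) table.
#' @return D' in `[0, 1]`.
#' @export
dprime_from_freqs <- function(f) {
  stopifnot(is.matrix(f), all(dim(f) == 2L), all(f >= 0))
  f <- f / sum(f)
  p1 <- f[1, 1] + f[1, 2]
  p2 <- f[1, 1] + f[2, 1]
  d <- f[1, 1] - p1 * p2
  d_max <- if (d >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
           else        min(p1 * p2, (1 - p1) * (1 - p2))
  if (d_max == 0) return(0)
  abs(d) / d_max
}

#' Simulate haplotypes for a region
#'
#' Draws `n_hap` haplotypes over the `spec$k` SNPs as a first-order Markov
#' chain: SNP 1 is Bernoulli(`maf[1]`) and each subsequent SNP is drawn from
#' the conditional distribution implied by [pair_haplotype_freqs()] for the
#' adjacent pair, given the allele at the previous SNP.
#'
#' @param spec a [region_spec()].
#' @param n_hap number of haplotypes (> 0).
#' @return `n_hap` x `k` integer matrix of 0/1 minor-allele indicators.
#' @export
simulate_haplotypes <- function(spec, n_hap) {
  stopifnot(inherits(spec, "region_spec"))
  n_hap <- as.integer(n_hap)
  if (is.na(n_hap) || n_hap <= 0L) stop("'n_hap' must be a positive integer")
  k <- spec$k
  h <- matrix(0L, n_hap, k)
  h[, 1L] <- rbinom(n_hap, 1L, spec$maf[1L])
  for (j in seq_len(k - 1L)) {
    f <- pair_haplotype_freqs(spec$maf[j], spec$maf[j + 1L], spec$dprime[j])
    p_given_minor <- f[1, 1] / (f[1, 1] + f[1, 2])
    p_given_major <- f[2, 1] / (f[2, 1] + f[2, 2])
    p_next <- ifelse(h[, j] == 1L, p_given_minor, p_given_major)
    h[, j + 1L] <- rbinom(n_hap, 1L, p_next)
  }
  colnames(h) <- paste0("snp", seq_len(k))
  h
}

#' Pair haplotypes into diploid genotype dosages
#'
#' Consecutive haplotype rows (1,2), (3,4), ... are paired into subjects
#' (random-union pairing, i.e. Hardy-Weinberg equilibrium), giving dosage
#' `g[i, j] = h[2i - 1, j] + h[2i, j]`.
#'
#' @param haps binary haplotype matrix with an even number of rows.
#' @param snp_ids optional SNP labels (defaults to haplotype column names).
#' @return A [genotype_matrix()] with `nrow(haps) / 2` subjects.
#' @export
haplotypes_to_genotypes <- function(haps, snp_ids = colnames(haps)) {
  stopifnot(is.matrix(haps))
  if (nrow(haps) %% 2L != 0L)
    stop("'haps' must have an even number of rows (two per subject)")
  if (!all(haps %in% c(0L, 1L))) stop("'haps' must be a 0/1 matrix")
  idx <- seq(1L, nrow(haps), by = 2L)
  g <- haps[idx, , drop = FALSE] + haps[idx + 1L, , drop = FALSE]
  genotype_matrix(g, snp_ids = snp_ids)
}

#' Simulate a diploid genotype matrix
#'
#' Convenience wrapper: `2n` haplotypes from [simulate_haplotypes()], paired by
#' [haplotypes_to_genotypes()].
#'
#' @param spec a [region_spec()].
#' @param n number of diploid subjects.
#' @return A [genotype_matrix()] (`n` subjects x `spec$k` SNPs).
#' @export
simulate_genotypes <- function(spec, n) {
  haplotypes_to_genotypes(simulate_haplotypes(spec, 2L * as.integer(n)))
}

#' Realized MAF and adjacent D-prime of a haplotype sample
#'
#' Frequency-counting estimates used to validate the simulator against its
#' region specification.
#'
#' @param haps binary haplotype matrix.
#' @return List with `maf` (length k) and `dprime` (length k - 1).
#' @export
haplotype_ld_summary <- function(haps) {
  stopifnot(is.matrix(haps), ncol(haps) >= 2L)
  maf <- colMeans(haps)
  k <- ncol(haps)
  dprime <- vapply(seq_len(k - 1L), function(j) {
    tab <- matrix(c(sum(haps[, j] == 1 & haps[, j + 1] == 1),
                    sum(haps[, j] == 1 & haps[, j + 1] == 0),
                    sum(haps[, j] == 0 & haps[, j + 1] == 1),
                    sum(haps[, j] == 0 & haps[, j + 1] == 0)),
                  2, 2, byrow = TRUE)
    dprime_from_freqs(tab)
  }, numeric(1))
  list(maf = maf, dprime = dprime)
}
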