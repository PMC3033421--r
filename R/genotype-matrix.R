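#' Genotype dosage matrix
#'
#' An `n x k` integer matrix of minor-allele dosages (0, 1 or 2), one row per
#' subject and one column per SNP, with SNP identifiers as column names and an
#' optional per-SNP position table carried as an attribute (used by the VCF
#' writer and the BED region mapper).
#'
#' @param dosages integer matrix with entries in \{0, 1, 2\}.
#' @param snp_ids character vector of SNP labels (default `snp1..snpk`).
#' @param positions optional data frame with columns `chrom` and `pos`
#'   (one row per SNP).
#' @return An object of class `genotype_matrix` (a matrix subclass).
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1), c(2, 1)))
#' n_subjects(g); n_snps(g)
#' @export
genotype_matrix <- function(dosages, snp_ids = NULL, positions = NULL) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1 or 2 (minor-allele copy number)")
  storage.mode(dosages) <- "integer"
  if (is.null(snp_ids)) {
    snp_ids <- colnames(dosages)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (length(snp_ids) != ncol(dosages))
    stop("'snp_ids' length must match the number of SNP columns")
  colnames(dosages) <- as.character(snp_ids)
  if (!is.null(positions)) {
    stopifnot(is.data.frame(positions), nrow(positions) == ncol(dosages),
              all(c("chrom", "pos") %in% names(positions)))
    attr(dosages, "positions") <- positions
  }
  class(dosages) <- c("genotype_matrix", class(dosages))
  dosages
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_subjects <- function(x) nrow(x)

#' @rdname genotype_matrix
#' @export
n_snps <- function(x) ncol(x)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "subjects x", ncol(x), "SNPs\n")
  maf <- colMeans(unclass(x)) / 2
  cat("sample MAF range: [", sprintf("%.3f", min(pmin(maf, 1 - maf))), ", ",
      sprintf("%.3f", max(pmin(maf, 1 - maf))), "]\n", sep = "")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  posinfo <- attr(m, "positions")
  attr(m, "positions") <- NULL
  out <- m[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  if (!is.null(posinfo) && !missing(j)) posinfo <- posinfo[j, , drop = FALSE]
  genotype_matrix(out, positions = posinfo)
}

# strip class for plain matrix algebra
geno_as_matrix <- function(geno) {
  m <- unclass(geno)
  attr(m, "positions") <- NULL
  m
}

#' Per-SNP sample minor-allele frequency
#'
#' @param geno a [genotype_matrix()].
#' @return Named numeric vector of dosage means divided by 2 (the allele-1
#'   frequency under the stored coding; equals the MAF when the stored allele
#'   is the minor one).
#' @export
sample_maf <- function(geno) colMeans(geno_as_matrix(geno)) / 2
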