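#' Read and write genotype matrices
#'
#' Two plain-text dialects are supported.  The TSV dialect is subjects x SNPs
#' with a header row of SNP identifiers and integer dosages 0/1/2.  The VCF
#' dialect is minimal VCF 4.2 with a GT FORMAT field and one sample column per
#' subject; the ALT allele is taken to be the dosage-counted (minor) allele,
#' multi-allelic records are rejected, and genotypes must be complete.
#' VCF parsing is delegated to the VariantAnnotation package.
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  write.table(geno_as_matrix(geno), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname genotype-io
#' @export
read_genotypes_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("genotype TSV must be numeric dosages")
  genotype_matrix(m, snp_ids = colnames(d))
}

#' @rdname genotype-io
#' @param chrom,pos_start contig name and first position used when the matrix
#'   carries no position table (positions then increment by 1000).
#' @export
write_genotypes_vcf <- function(geno, path, chrom = "1", pos_start = 1000L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno_as_matrix(geno)
  k <- ncol(g); n <- nrow(g)
  posinfo <- attr(geno, "positions")
  if (is.null(posinfo))
    posinfo <- data.frame(chrom = chrom,
                          pos = pos_start + 1000L * (seq_len(k) - 1L))
  gt <- c("0/0", "0/1", "1/1")[g + 1L]
  dim(gt) <- dim(g)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste0("##contig=<ID=", unique(posinfo$chrom), ">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("S", seq_len(n))),
                   collapse = "\t"))
  body <- vapply(seq_len(k), function(j) {
    paste(c(posinfo$chrom[j], posinfo$pos[j], colnames(g)[j], "A", "G",
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname genotype-io
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt) > 1L))
    stop("multi-allelic VCF records are not supported")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 0L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L
  if (any(is.na(dosage)))
    stop("missing or unrecognized GT codes; complete biallelic GT required")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  genotype_matrix(t(dosage), snp_ids = ids,
                  positions = data.frame(
                    chrom = as.character(GenomeInfoDb::seqnames(rr)),
                    pos = BiocGenerics::start(rr)))
}

#' Read and write quantitative trait vectors
#'
#' One-column TSV with a header line; subject order must match the genotype
#' file's row order.
#'
#' @param y numeric trait vector.
#' @param path file path.
#' @name trait-io
NULL

#' @rdname trait-io
#' @export
write_trait_tsv <- function(y, path) {
  write.table(data.frame(trait = as.numeric(y)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trait-io
#' @export
read_trait_tsv <- function(path) {
  d <- read.delim(path)
  if (ncol(d) != 1L) stop("trait TSV must have exactly one column")
  y <- as.numeric(d[[1]])
  if (any(!is.finite(y))) stop("trait values must be finite")
  y
}

#' Read a gene-to-SNP region map
#'
#' Explicit mapping format: a TSV with columns `gene` and `snps`, the latter a
#' comma-separated list of SNP identifiers.  BED mode (`format = "bed"`)
#' expects columns chrom, start, end, gene (0-based half-open intervals) and
#' requires genotype positions (`positions` from a VCF read) to resolve SNPs.
#'
#' @param path file path.
#' @param format `"list"` (default) or `"bed"`.
#' @param geno genotype matrix whose SNP positions resolve BED intervals.
#' @return Named list mapping gene id to a character vector of SNP ids.
#' @export
read_regions <- function(path, format = c("list", "bed"), geno = NULL) {
  format <- match.arg(format)
  if (format == "list") {
    d <- read.delim(path, colClasses = "character")
    if (!all(c("gene", "snps") %in% names(d)))
      stop("region list TSV needs columns 'gene' and 'snps'")
    out <- lapply(d$snps, function(s) trimws(strsplit(s, ",")[[1]]))
    names(out) <- d$gene
    return(out)
  }
  if (is.null(geno) || is.null(attr(geno, "positions")))
    stop("BED regions need genotypes with SNP positions (read from VCF)")
  bed <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(bed) < 4L) stop("BED region file needs chrom, start, end, gene")
  names(bed)[1:4] <- c("chrom", "start", "end", "gene")
  posinfo <- attr(geno, "positions")
  out <- lapply(seq_len(nrow(bed)), function(i) {
    s <- as.integer(bed$start[i]); e <- as.integer(bed$end[i])
    hit <- posinfo$chrom == bed$chrom[i] & posinfo$pos > s & posinfo$pos <= e
    colnames(geno)[hit]
  })
  names(out) <- bed$gene
  out
}
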