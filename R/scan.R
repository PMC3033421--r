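#' Gene-panel / genome scan with pooled-permutation FDR
#'
#' Runs the PLS-based multilocus test gene by gene: for each gene the matching
#' SNP columns are extracted, the observed F statistic and `B` permutation
#' statistics are computed (the *same* machinery for every gene so statistics
#' are poolable), the per-gene empirical p-value is the add-one permutation
#' p, and q-values come from [pooled_fdr()] across all genes and permutations.
#' Genes with `q <= fdr_level` are flagged significant.
#'
#' @param geno a [genotype_matrix()] covering all scanned SNPs.
#' @param y trait vector, subject order matching `geno` rows.
#' @param regions named list mapping gene id to a character vector of SNP ids
#'   (see [read_regions()]); genes matching no SNP column are skipped with a
#'   warning.
#' @param B permutations per gene.
#' @param seed root seed; gene g uses `derive_seed(seed, g)`.
#' @param m PLS components per gene; with `m_rule = "variance"` the count is
#'   instead chosen per gene by [select_m_by_variance()] at `threshold`.
#' @param m_rule `"fixed"` (default) or `"variance"`.
#' @param threshold genotype-variance threshold for `m_rule = "variance"`.
#' @param fdr_level significance cut on the monotonized q-value.
#' @return Data frame with `gene`, `n_snps`, `m`, `statistic`, `p`, `q_raw`,
#'   `q`, `significant`, one row per scanned gene.
#' @export
genome_scan <- function(geno, y, regions, B = 2000L, seed = 1L,
                        m = 1L, m_rule = c("fixed", "variance"),
                        threshold = 0.8, fdr_level = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m_rule <- match.arg(m_rule)
  y <- as.numeric(y)
  if (length(y) != n_subjects(geno))
    stop("subject count mismatch between genotypes and trait")
  if (!length(regions)) stop("empty region map")
  genes <- names(regions)
  keep <- vapply(regions, function(s) sum(colnames(geno) %in% s) > 0,
                 logical(1))
  if (any(!keep))
    warning("skipping ", sum(!keep), " region(s) with no matched SNPs: ",
            paste(genes[!keep], collapse = ", "))
  genes <- genes[keep]
  if (!length(genes)) stop("no region matched any SNP column")

  stats <- numeric(length(genes))
  pvals <- numeric(length(genes))
  msel <- integer(length(genes))
  nsnp <- integer(length(genes))
  perm <- matrix(NA_real_, length(genes), B)
  for (gi in seq_along(genes)) {
    cols <- which(colnames(geno) %in% regions[[genes[gi]]])
    sub <- genotype_matrix(geno_as_matrix(geno)[, cols, drop = FALSE])
    m_g <- if (m_rule == "variance") {
      fit <- fit_pls(sub, y, m = min(n_subjects(sub) - 1L, n_snps(sub)))
      max(1L, select_m_by_variance(fit, threshold))
    } else as.integer(m)
    res <- mlas_test(sub, y, "PLS_MLAS", B = B,
                     seed = derive_seed(seed, gi), m = m_g,
                     return_permuted = TRUE)
    stats[gi] <- res$statistic
    pvals[gi] <- res$empirical_p
    perm[gi, ] <- res$permuted
    msel[gi] <- m_g
    nsnp[gi] <- length(cols)
  }
  fdr <- pooled_fdr(stats, perm)
  data.frame(gene = genes, n_snps = nsnp, m = msel, statistic = stats,
             p = pvals, q_raw = fdr$q_raw, q = fdr$q,
             significant = fdr$q <= fdr_level, row.names = NULL)
}

#' Write a scan result table with a config echo header
#'
#' @param result data frame from [genome_scan()].
#' @param path output TSV path.
#' @param config named list echoed as `# key: value` comment lines.
#' @export
write_scan_tsv <- function(result, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s: %s", k, paste(config[[k]], collapse = " ")), con)
  write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
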