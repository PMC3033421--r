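Package: plsmlas
Title: Partial Least-Squares Multilocus Association Testing for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Developers", "plsmlas", email = "plsmlas@example.org", role = c("aut", "cre"))
Description: Gene- or region-level multilocus association tests for quantitative
    traits. Genotype dosages within a candidate region are decomposed into
    partial least-squares (PLS) components that maximize covariance with the
    trait; the leading components are carried into a low-degree-of-freedom
    multilinear regression whose overall F statistic is calibrated by trait
    permutation. Comparator tests (principal-component regression, greedy
    r-squared tagSNP regression, and tail-strength-measure tests built on
    per-SNP F or Wald p-values), pooled-permutation false-discovery-rate
    q-values for multi-gene scans, a linkage-disequilibrium-aware diploid
    genotype simulator with additive and epistatic trait models, and a
    power/type-I-error study driver are included, together with TSV and VCF
    input/output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
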