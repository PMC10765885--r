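Package: dacepop
Title: Population Genomics of Desert-Spring Dace
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control, diversity and differentiation statistics, and
    demographic inference utilities for reduced-representation SNP panels from
    small, fragmented fish populations. Implements per-population genotype
    filtering with KING-robust relative pruning, observed/expected
    heterozygosity and F_IS, pairwise Weir-Cockerham F_ST with a
    neighbor-joining dendrogram, allele-frequency PCA, the single-sample
    linkage-disequilibrium effective population size estimator with the
    Waples bias correction, the outgroup-free three-sample D3 gene-flow
    statistic over individual trios, joint site-frequency spectra with
    hypergeometric projection and SNP bootstrap, and a discrete-generation
    structured-coalescent simulator whose shipped presets encode fitted
    multi-population demographic histories so that every stage can be
    exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vcfR,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
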