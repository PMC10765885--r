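# fixture builders shared across test files; everything is generated in code

# quick GenotypeMatrix from a samples-in-columns integer matrix
makeGM <- function(gt, pops, ...) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("L%03d", seq_len(nrow(gt)))
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("s%03d", seq_len(ncol(gt)))
  GenotypeMatrix(gt, population = pops, ...)
}

# random Hardy-Weinberg panel: loci x samples dosages, locus freqs U(0.1, 0.9)
hweGM <- function(nLoci, nSamples, pops = rep("P", nSamples),
                  missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(nLoci, 0.1, 0.9)
  gt <- matrix(rbinom(nLoci * nSamples, 2L, rep(p, nSamples)),
               nLoci, nSamples)
  if (missing > 0) gt[runif(length(gt)) < missing] <- NA_integer_
  makeGM(gt, pops)
}

# three-population clean-divergence history (sisters A, B; outgroup C),
# constant diploid size everywhere, optional forward C -> A migration band
threePopModel <- function(N = 1000, T2 = 294, T1 = 1892, migCA = 0) {
  mig <- if (migCA > 0)
    data.frame(t0 = 0, t1 = T2, from = "C", to = "A", rate = migCA)
  else data.frame()
  demographicModel(
    c("A", "B", "C", "AB", "ANC"),
    data.frame(pop = c("A", "B", "C", "AB", "ANC"),
               t0 = c(0, 0, 0, T2, T1), t1 = c(T2, T2, T1, T1, Inf),
               n0 = N, n1 = N, type = "constant"),
    merges = data.frame(time = c(T2, T2, T1, T1),
                        from = c("A", "B", "AB", "C"),
                        to = c("AB", "AB", "ANC", "ANC")),
    migration = mig)
}

# two-population split, constant size N, divergence T generations
twoPopModel <- function(N, T, mu = 1e-5) {
  demographicModel(
    c("A", "B", "ANC"),
    data.frame(pop = c("A", "B", "ANC"), t0 = c(0, 0, T),
               t1 = c(T, T, Inf), n0 = N, n1 = N, type = "constant"),
    merges = data.frame(time = c(T, T), from = c("A", "B"),
                        to = c("ANC", "ANC")),
    mu = mu)
}

# minimal VCF text for IO tests
testVcfLines <- function(siteRows, samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    siteRows)
}
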