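#' Per-population heterozygosity and inbreeding
#'
#' For each population and locus with `n >= 2` called diploids and alternate
#' allele frequency `p`, computes observed heterozygosity `H_O = n_het / n`
#' and Nei's unbiased expected heterozygosity
#' `H_E = 2 p (1 - p) * 2n / (2n - 1)`. Monomorphic loci contribute 0 to
#' both. Population summaries average over all qualifying loci
#' (polymorphic or not) and the inbreeding coefficient is the
#' ratio-of-means form `F_IS = 1 - mean(H_O) / mean(H_E)` (0 when the mean
#' expected heterozygosity is 0), which is stable for low-diversity loci;
#' per-locus values are returned for diagnostics.
#'
#' @param g a [GenotypeMatrix]; every population needs at least 2 genotyped
#'   samples at some locus.
#' @return A list with `summary` (data.frame: population, n_samples,
#'   n_loci_used, H_O, H_E, F_IS) and `per_locus` (list of per-population
#'   data.frames with locus-wise n, p, H_O, H_E).
#' @examples
#' g <- GenotypeMatrix(matrix(c(1L, 1L), 1, 2,
#'        dimnames = list("s1", c("a", "b"))), population = c("P", "P"))
#' diversitySummary(g)$summary  # H_O = 1, H_E = 2/3, F_IS = -0.5
#' @export
diversitySummary <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  gt <- genotypes(g)
  popIdx <- .popIndex(g)
  st <- .popLocusStats(gt, popIdx)
  perLocus <- lapply(st, function(s) {
    use <- s$n >= 2L
    ho <- ifelse(use, s$het / s$n, NA_real_)
    he <- ifelse(use,
                 2 * s$p * (1 - s$p) * (2 * s$n) / (2 * s$n - 1),
                 NA_real_)
    data.frame(locus = rownames(gt), n = s$n, p = s$p,
               H_O = ho, H_E = he, row.names = NULL)
  })
  summary <- do.call(rbind, lapply(names(perLocus), function(pop) {
    pl <- perLocus[[pop]]
    use <- !is.na(pl$H_O)
    mho <- mean(pl$H_O[use])
    mhe <- mean(pl$H_E[use])
    fis <- if (isTRUE(mhe > 0)) 1 - mho / mhe else 0
    data.frame(population = pop, n_samples = length(popIdx[[pop]]),
               n_loci_used = sum(use), H_O = mho, H_E = mhe, F_IS = fis)
  }))
  rownames(summary) <- NULL
  list(summary = summary, per_locus = perLocus)
}
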