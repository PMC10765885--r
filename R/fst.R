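#' Weir-Cockerham variance components for one locus
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the 1984 two-level
#' moment estimator for diploids, from per-population sample sizes, alternate
#' allele frequencies and observed heterozygote frequencies.
#'
#' @param n integer vector of called diploids per population (all >= 2).
#' @param p alternate allele frequency per population.
#' @param h observed heterozygote frequency per population.
#' @return Named numeric vector `c(a, b, c)`.
#' @keywords internal
.wcComponents <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham F_ST
#'
#' For every pair of populations, computes the weighted (ratio-of-sums)
#' multi-locus Weir-Cockerham theta: per-locus variance components a, b, c
#' are accumulated over loci at which both populations have at least 2
#' called diploids, and theta = sum(a) / sum(a + b + c). Loci monomorphic
#' across the pair contribute zero components and are excluded from the
#' sums. Estimates can be slightly negative for undifferentiated pairs;
#' raw values are reported unclipped (clipping to zero happens only when a
#' matrix is used as a distance, see [njDendrogram()]).
#'
#' @param g a [GenotypeMatrix] with at least 2 populations, each with at
#'   least 2 genotyped samples.
#' @return A list with `fst` (symmetric matrix of pairwise theta, zero
#'   diagonal) and `n_loci` (matrix of locus counts entering each pair).
#' @examples
#' g <- GenotypeMatrix(matrix(c(0L, 0L, 2L, 2L), 1, 4,
#'        dimnames = list("s1", paste0("i", 1:4))),
#'        population = c("A", "A", "B", "B"))
#' pairwiseFst(g)$fst  # fixed difference: theta = 1
#' @export
pairwiseFst <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  gt <- genotypes(g)
  popIdx <- .popIndex(g)
  if (length(popIdx) < 2L) stop("at least two populations are required")
  st <- .popLocusStats(gt, popIdx)
  pops <- names(popIdx)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  nl <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    si <- st[[i]]; sj <- st[[j]]
    use <- si$n >= 2L & sj$n >= 2L
    # polymorphic within the pair
    poly <- use & !((si$p %in% c(0, 1)) & (sj$p == si$p))
    if (!any(poly)) {
      fst[i, j] <- fst[j, i] <- NA_real_
      next
    }
    idx <- which(poly)
    comps <- vapply(idx, function(l) {
      .wcComponents(c(si$n[l], sj$n[l]),
                    c(si$p[l], sj$p[l]),
                    c(si$het[l] / si$n[l], sj$het[l] / sj$n[l]))
    }, numeric(3))
    theta <- sum(comps["a", ]) / sum(colSums(comps))
    fst[i, j] <- fst[j, i] <- theta
    nl[i, j] <- nl[j, i] <- length(idx)
  }
  list(fst = fst, n_loci = nl)
}
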