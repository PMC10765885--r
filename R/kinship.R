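#' KING-robust pairwise kinship
#'
#' Estimates the kinship coefficient phi for every pair of samples with the
#' structure-robust within-pair estimator
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where, over the loci called in both samples, \eqn{N_{Aa,Aa}} counts loci
#' at which both are heterozygous, \eqn{N_{AA,aa}} counts opposite
#' homozygotes, and \eqn{N_{Aa}(\cdot)} counts heterozygous loci in each
#' sample. Duplicate samples give phi = 0.5; unrelated individuals from the
#' same population give phi near 0; phi is invariant to swapping allele
#' labels at any locus.
#'
#' Degrees follow the standard powers-of-1/2 midpoint cutoffs: duplicate
#' phi > 0.354, 1st degree (0.177, 0.354], 2nd degree (0.0884, 0.177],
#' otherwise unrelated. Pairs sharing no heterozygous locus have an
#' undefined phi; they are returned with `phi = NA`, degree `"unrelated"`
#' and `undefined = TRUE`.
#'
#' @param g a [GenotypeMatrix] with at least two samples.
#' @return A `data.frame` (one row per unordered pair) with columns
#'   `sample_i`, `sample_j`, `n_loci` (shared called loci), `phi`, `degree`
#'   and `undefined`.
#' @seealso [pruneRelatives()]
#' @export
kingKinship <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  gt <- genotypes(g)
  n <- ncol(gt)
  if (n < 2L) stop("at least two samples are required")
  called <- !is.na(gt)
  het <- gt == 1L & called
  hom0 <- gt == 0L & called
  hom2 <- gt == 2L & called
  # cross-products give all pairwise shared counts in one pass
  C <- crossprod(called)            # shared called loci
  HH <- crossprod(het)              # both heterozygous
  OPP <- crossprod(hom0, hom2)      # i is 0/0, j is 1/1
  OPP <- OPP + t(OPP)               # opposite homozygotes either way
  # het counts restricted to loci called in the partner
  HETI <- crossprod(het, called)    # rows: het in i over loci called in j
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  denom <- HETI[i + (j - 1L) * n] + HETI[j + (i - 1L) * n]
  num <- HH[pairs] - 2 * OPP[pairs]
  phi <- ifelse(denom > 0, num / denom, NA_real_)
  degree <- rep("unrelated", length(phi))
  degree[!is.na(phi) & phi > 0.0884] <- "second"
  degree[!is.na(phi) & phi > 0.177] <- "first"
  degree[!is.na(phi) & phi > 0.354] <- "duplicate"
  data.frame(sample_i = colnames(gt)[i], sample_j = colnames(gt)[j],
             n_loci = C[pairs], phi = phi, degree = degree,
             undefined = denom == 0, stringsAsFactors = FALSE)
}

#' Greedy relative pruning
#'
#' Removes one member of every related pair (phi strictly above the cutoff)
#' by repeatedly deleting the sample involved in the most flagged pairs,
#' breaking ties by lexicographic sample id, until no flagged pair remains.
#' An isolated related pair therefore loses exactly one member, and a
#' "star" of relatives loses only its hub.
#'
#' @param g a [GenotypeMatrix].
#' @param kin kinship table from [kingKinship()] computed on `g`.
#' @param cfg a [qcConfig()]; `kinshipCutoff` sets the flagging threshold.
#' @return A list with `genotypes` (pruned [GenotypeMatrix]) and `removed`
#'   (character vector, in removal order).
#' @export
pruneRelatives <- function(g, kin = kingKinship(g), cfg = qcConfig()) {
  stopifnot(is(g, "GenotypeMatrix"))
  flagged <- kin[!is.na(kin$phi) & kin$phi > cfg@kinshipCutoff,
                 c("sample_i", "sample_j"), drop = FALSE]
  removed <- character()
  while (nrow(flagged) > 0) {
    cnt <- table(c(flagged$sample_i, flagged$sample_j))
    top <- names(cnt)[cnt == max(cnt)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    flagged <- flagged[flagged$sample_i != victim &
                       flagged$sample_j != victim, , drop = FALSE]
  }
  list(genotypes = g[, setdiff(colnames(g), removed)], removed = removed)
}
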