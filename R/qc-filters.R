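#' Locus-level QC filtering
#'
#' Applies the post-assembly locus filters in a fixed order and reports how
#' many loci each rule removed (counted sequentially, i.e. each rule sees
#' only the survivors of the previous one):
#'
#' 1. **per-population call rate**: the fraction of called genotypes must be
#'    at least `minCallRate` in (by default) every population;
#' 2. **minor-allele count**: the pooled count of the rarer allele over all
#'    non-missing genotypes must be at least `minMAC`;
#' 3. **depth**: loci whose `mean_depth` exceeds the across-locus
#'    `mean + depthSDThreshold * SD` are removed (a screen against merged
#'    paralogs); silently skipped when no depth metadata are present;
#' 4. **first SNP per locus**: within each `locus_group` only the first SNP
#'    in input order is kept, so retained SNPs are independent.
#'
#' The call-rate and MAC rules are order-independent; the report simply
#' attributes each removal to the first rule that caught it.
#'
#' @param g a [GenotypeMatrix].
#' @param cfg a [qcConfig()] object.
#' @return A list with elements `genotypes` (the filtered [GenotypeMatrix])
#'   and `report` (named integer vector of removals per rule, plus
#'   `loci_in` / `loci_out`).
#' @examples
#' g <- GenotypeMatrix(matrix(c(0L,0L,0L,1L), 1, 4,
#'        dimnames = list("s1", paste0("i", 1:4))),
#'        population = rep("A", 4))
#' filterLoci(g, qcConfig(minCallRate = 0))$report  # MAC 1 < 3: removed
#' @export
filterLoci <- function(g, cfg = qcConfig()) {
  stopifnot(is(g, "GenotypeMatrix"), is(cfg, "QcConfig"))
  gt <- genotypes(g)
  report <- c(call_rate = 0L, mac = 0L, depth = 0L, first_snp = 0L)
  keep <- rep(TRUE, nrow(gt))

  # per-population call rate
  popIdx <- .popIndex(g)
  need <- if (is.na(cfg@minPopulations)) length(popIdx)
          else min(cfg@minPopulations, length(popIdx))
  okPops <- Reduce(`+`, lapply(popIdx, function(idx) {
    sub <- gt[, idx, drop = FALSE]
    as.integer(rowMeans(!is.na(sub)) >= cfg@minCallRate)
  }))
  pass <- okPops >= need
  report["call_rate"] <- sum(keep & !pass)
  keep <- keep & pass

  # pooled minor allele count
  alt <- rowSums(gt, na.rm = TRUE)
  called <- rowSums(!is.na(gt))
  mac <- pmin(alt, 2L * called - alt)
  pass <- mac >= cfg@minMAC
  report["mac"] <- sum(keep & !pass)
  keep <- keep & pass

  # excess depth (paralog screen)
  md <- meanDepth(g)
  if (!is.null(md)) {
    lim <- mean(md, na.rm = TRUE) +
      cfg@depthSDThreshold * sd(md, na.rm = TRUE)
    pass <- is.na(md) | md <= lim
    report["depth"] <- sum(keep & !pass)
    keep <- keep & pass
  }

  # one SNP per assembly locus, first in input order
  if (cfg@firstSNPOnly) {
    grp <- locusGroups(g)
    first <- !duplicated(grp[keep])
    idxKeep <- which(keep)
    report["first_snp"] <- sum(!first)
    keep[idxKeep[!first]] <- FALSE
  }

  out <- g[keep, ]
  list(genotypes = out,
       report = c(as.list(report),
                  loci_in = nrow(gt), loci_out = sum(keep)))
}

#' Sample-level QC filtering
#'
#' Removes samples whose genotyping rate (non-missing fraction over loci) is
#' strictly below `minSampleCallRate`; a sample at exactly the cutoff is
#' retained.
#'
#' @inheritParams filterLoci
#' @return A list with `genotypes` (filtered [GenotypeMatrix]), `removed`
#'   (character vector of dropped sample ids) and `report`.
#' @export
filterSamples <- function(g, cfg = qcConfig()) {
  stopifnot(is(g, "GenotypeMatrix"), is(cfg, "QcConfig"))
  gt <- genotypes(g)
  rate <- colMeans(!is.na(gt))
  drop <- rate < cfg@minSampleCallRate
  if (all(drop))
    stop("all samples fall below the genotyping-rate cutoff (",
         cfg@minSampleCallRate, "); cannot proceed")
  list(genotypes = g[, !drop],
       removed = colnames(g)[drop],
       report = list(samples_in = ncol(g), samples_removed = sum(drop),
                     samples_out = sum(!drop)))
}
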