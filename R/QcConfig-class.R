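#' QC configuration for genotype filtering
#'
#' Bundles the post-assembly filtering thresholds applied by [filterLoci()],
#' [filterSamples()] and [pruneRelatives()]. The defaults are the standard
#' stringent GBS panel settings: a locus must be called in at least 80% of
#' the samples of every population, carry a pooled minor-allele count of at
#' least 3, not exceed the across-locus mean depth by more than 2 SD
#' (paralog screen), and only the first SNP of each assembly locus is kept;
#' samples genotyped at under 70% of loci are dropped, and one member of
#' every pair related at 2nd degree or closer (KING-robust phi > 0.0884) is
#' pruned.
#'
#' @param minCallRate minimum per-population call-rate fraction for a locus
#'   (non-strict: exactly the cutoff is retained).
#' @param minPopulations number of populations that must meet `minCallRate`;
#'   `NA` (default) means all populations present.
#' @param minMAC minimum minor-allele count, counted over all samples pooled.
#' @param depthSDThreshold loci whose mean depth exceeds
#'   `mean + depthSDThreshold * SD` of per-locus depths are removed (only
#'   when depth metadata are present).
#' @param minSampleCallRate samples with non-missing fraction strictly below
#'   this are removed.
#' @param kinshipCutoff KING-robust kinship above which a pair is treated as
#'   related (default 0.0884, the 2nd-degree boundary).
#' @param firstSNPOnly keep only the first SNP (input order) per
#'   `locus_group`.
#'
#' @return A `QcConfig` object.
#' @examples
#' qcConfig()
#' qcConfig(minMAC = 5L)
#' @export
qcConfig <- function(minCallRate = 0.80, minPopulations = NA_integer_,
                     minMAC = 3L, depthSDThreshold = 2.0,
                     minSampleCallRate = 0.70, kinshipCutoff = 0.0884,
                     firstSNPOnly = TRUE) {
  new("QcConfig",
      minCallRate = minCallRate,
      minPopulations = as.integer(minPopulations),
      minMAC = as.integer(minMAC),
      depthSDThreshold = depthSDThreshold,
      minSampleCallRate = minSampleCallRate,
      kinshipCutoff = kinshipCutoff,
      firstSNPOnly = firstSNPOnly)
}

#' @rdname qcConfig
#' @export
setClass("QcConfig", representation(
  minCallRate = "numeric",
  minPopulations = "integer",
  minMAC = "integer",
  depthSDThreshold = "numeric",
  minSampleCallRate = "numeric",
  kinshipCutoff = "numeric",
  firstSNPOnly = "logical"))

setValidity("QcConfig", function(object) {
  msg <- character()
  if (object@minCallRate < 0 || object@minCallRate > 1)
    msg <- c(msg, "minCallRate must lie in [0, 1]")
  if (object@minSampleCallRate < 0 || object@minSampleCallRate > 1)
    msg <- c(msg, "minSampleCallRate must lie in [0, 1]")
  if (object@minMAC < 0L) msg <- c(msg, "minMAC must be >= 0")
  if (object@depthSDThreshold <= 0)
    msg <- c(msg, "depthSDThreshold must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QcConfig", function(object) {
  cat("QcConfig:\n",
      sprintf("  locus call rate >= %.2f in %s populations\n",
              object@minCallRate,
              if (is.na(object@minPopulations)) "all"
              else object@minPopulations),
      sprintf("  pooled minor allele count >= %d\n", object@minMAC),
      sprintf("  depth <= mean + %.1f SD\n", object@depthSDThreshold),
      sprintf("  sample call rate >= %.2f (strict removal below)\n",
              object@minSampleCallRate),
      sprintf("  kinship pruning at phi > %.4f\n", object@kinshipCutoff),
      sprintf("  first SNP per locus: %s\n", object@firstSNPOnly), sep = "")
})
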