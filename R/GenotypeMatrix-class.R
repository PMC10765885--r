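#' GenotypeMatrix: diploid biallelic SNP genotypes with population labels
#'
#' An S4 container for a diploid biallelic genotype panel, extending
#' [SummarizedExperiment::SummarizedExperiment]. The single assay `"GT"` holds
#' alternate-allele dosages coded 0, 1, 2 with `NA` for missing calls; rows
#' are SNPs (loci) and columns are samples. `colData` carries the mandatory
#' `population` label per sample; `rowData` carries the assembly-locus tag
#' (`locus_group`, used by the one-SNP-per-locus filter), optional `chrom` /
#' `pos` coordinates and optional per-locus `mean_depth` (x coverage).
#'
#' All statistics in the package are invariant to swapping the allele labels
#' (recoding a locus 0<->2) unless documented otherwise.
#'
#' @param genotypes integer matrix of dosages, loci x samples, values in
#'   \{0, 1, 2, NA\}. Dimnames are used as locus and sample identifiers;
#'   defaults are generated when absent.
#' @param population character vector of population labels, one per sample
#'   (recycled names from `colnames(genotypes)` if named).
#' @param locusGroup optional character vector tagging each SNP with the
#'   assembly locus it came from; defaults to one group per SNP.
#' @param chrom,pos optional per-locus coordinates.
#' @param meanDepth optional nonnegative per-locus mean sequencing depth.
#'
#' @return A `GenotypeMatrix` object.
#' @examples
#' g <- GenotypeMatrix(
#'   matrix(c(0L, 1L, 2L, NA, 1L, 1L), nrow = 3,
#'          dimnames = list(paste0("snp", 1:3), c("s1", "s2"))),
#'   population = c("A", "A"))
#' g
#' genotypes(g)
#' populations(g)
#' @aliases GenotypeMatrix genotypes populations locusGroups meanDepth
#'   nSamples nLoci
#' @export
GenotypeMatrix <- function(genotypes, population, locusGroup = NULL,
                           chrom = NULL, pos = NULL, meanDepth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("locus%d", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("sample%d", seq_len(ncol(genotypes)))
  if (!is.null(names(population)))
    population <- population[colnames(genotypes)]
  if (length(population) != ncol(genotypes))
    stop("'population' must supply one label per sample")
  if (is.null(locusGroup)) locusGroup <- rownames(genotypes)
  rd <- DataFrame(locus_group = as.character(locusGroup))
  if (!is.null(chrom)) rd$chrom <- as.character(chrom)
  if (!is.null(pos)) rd$pos <- as.integer(pos)
  if (!is.null(meanDepth)) rd$mean_depth <- as.numeric(meanDepth)
  se <- SummarizedExperiment(
    assays = list(GT = genotypes),
    rowData = rd,
    colData = DataFrame(population = as.character(population),
                        row.names = colnames(genotypes)))
  new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' is required")
  gt <- assay(object, "GT")
  if (!is.integer(gt))
    msg <- c(msg, "genotypes must be stored as integers")
  bad <- gt[!is.na(gt)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (ncol(object) < 1L)
    msg <- c(msg, "at least one sample is required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (nrow(object) > 0L &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "locus identifiers must be present and unique")
  if (!"population" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  else if (anyNA(colData(object)$population))
    msg <- c(msg, "every sample needs a population label")
  if (!"locus_group" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'locus_group' column")
  if ("mean_depth" %in% colnames(rowData(object))) {
    md <- rowData(object)$mean_depth
    if (any(md[!is.na(md)] < 0))
      msg <- c(msg, "mean_depth must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix`.
#' @param ... unused.
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x, ...) assay(x, "GT"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("populations", "GenotypeMatrix", function(x, ...)
  setNames(colData(x)$population, colnames(x)))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("locusGroups", "GenotypeMatrix", function(x, ...)
  setNames(rowData(x)$locus_group, rownames(x)))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("meanDepth", "GenotypeMatrix", function(x, ...) {
  if (!"mean_depth" %in% colnames(rowData(x))) return(NULL)
  setNames(rowData(x)$mean_depth, rownames(x))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) ncol(x))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nLoci", "GenotypeMatrix", function(x) nrow(x))

setMethod("show", "GenotypeMatrix", function(object) {
  gt <- genotypes(object)
  miss <- if (length(gt)) mean(is.na(gt)) else 0
  cat(sprintf("GenotypeMatrix: %d loci x %d samples (%.1f%% missing)\n",
              nrow(object), ncol(object), 100 * miss))
  tab <- table(populations(object))
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(meanDepth(object)))
    cat(sprintf("mean depth: %.1fx (per-locus metadata present)\n",
                mean(meanDepth(object), na.rm = TRUE)))
})

# sample indices per population, in colData order
.popIndex <- function(g) split(seq_len(ncol(g)), populations(g))

# per-population allele frequency / call summaries for one dosage matrix
# returns list(n = called diploids, p = alt frequency, het = het counts)
.popLocusStats <- function(gt, popIdx) {
  lapply(popIdx, function(idx) {
    sub <- gt[, idx, drop = FALSE]
    called <- !is.na(sub)
    n <- rowSums(called)
    alt <- rowSums(sub, na.rm = TRUE)
    het <- rowSums(sub == 1L, na.rm = TRUE)
    list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_), het = het)
  })
}
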