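#' PCA of allele dosages
#'
#' Principal component analysis of the sample-by-locus dosage matrix.
#' Missing genotypes are imputed with the sample's population mean dosage at
#' that locus (the global locus mean when a population is entirely
#' uncalled); columns are then centered and scaled to unit variance, with
#' zero-variance columns dropped rather than erroring. Component signs are
#' fixed so the first sample's score is nonnegative on every component,
#' making results reproducible across platforms.
#'
#' @param g a [GenotypeMatrix] with at least 2 samples.
#' @param nComponents number of components to return (capped by the rank).
#' @return A list with `scores` (samples x components), `explained`
#'   (fraction of variance per component) and `n_loci_used`.
#' @export
pcaAlleleFreq <- function(g, nComponents = 10L) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (ncol(g) < 2L) stop("at least two samples are required")
  gt <- genotypes(g)
  X <- t(gt)  # samples x loci
  pop <- populations(g)
  # population-mean imputation
  for (p in unique(pop)) {
    rows <- which(pop == p)
    sub <- X[rows, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    glob <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- glob[is.nan(mu)]
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- mu[idx[, 2]]
    X[rows, ] <- sub
  }
  keep <- apply(X, 2, function(col) var(col) > 0 && !anyNA(col))
  if (!any(keep)) stop("all loci have zero variance after imputation")
  X <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  nc <- min(nComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  flip <- ifelse(scores[1, ] < 0, -1, 1)
  scores <- sweep(scores, 2, flip, `*`)
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)]
  list(scores = scores, explained = explained, n_loci_used = sum(keep))
}

#' Neighbor-joining dendrogram from an F_ST matrix
#'
#' Builds a population-level NJ tree from pairwise F_ST. Negative F_ST
#' estimates are floored at 0 for use as distances (raw values are never
#' altered elsewhere). Negative branch lengths produced by the
#' agglomeration are clamped to 0 with the deficit transferred to the
#' sibling branch, the standard practice preserving adjacent-pair path
#' lengths.
#'
#' @param fst symmetric matrix of pairwise F_ST with population dimnames
#'   (e.g. `pairwiseFst(g)$fst`), at least 3 populations.
#' @return A newick string (unrooted tree with branch lengths).
#' @export
njDendrogram <- function(fst) {
  if (!is.matrix(fst) || nrow(fst) != ncol(fst))
    stop("'fst' must be a square matrix")
  if (nrow(fst) < 3L) stop("at least 3 populations are required")
  d <- pmax(fst, 0)
  tree <- ape::nj(as.dist(d))
  tree <- .clampNegativeEdges(tree)
  ape::write.tree(tree)
}

# clamp negative edge lengths to zero, moving the deficit onto the sibling
# edge so the path length between the two siblings is preserved
.clampNegativeEdges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]  # negative
    tree$edge.length[e] <- 0
    if (length(sibs))
      tree$edge.length[sibs[1]] <-
        max(0, tree$edge.length[sibs[1]] + deficit)
  }
  tree
}
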