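#' Pairwise identity-by-state genetic distances
#'
#' Allele-sharing IBS distance between individuals:
#' `d(i, j) = mean over shared called loci of |g_i - g_j| / 2`, so identical
#' genotypes score 0, a heterozygote against either homozygote scores 0.5
#' and opposite homozygotes score 1. Distances lie in \[0, 1\] and are
#' invariant to allele-label swaps.
#'
#' @param g a [GenotypeMatrix] with at least two samples.
#' @return A list with `d` (symmetric distance matrix, zero diagonal) and
#'   `n_loci` (per-pair count of shared called loci). Pairs sharing no
#'   called locus raise an error naming them.
#' @export
ibsDistance <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  gt <- genotypes(g)
  if (ncol(gt) < 2L) stop("at least two samples are required")
  parts <- .ibsParts(gt)
  L <- parts$L
  if (any(L[upper.tri(L)] == 0)) {
    bad <- which(upper.tri(L) & L == 0, arr.ind = TRUE)
    stop("no shared called loci for pair(s): ",
         paste(sprintf("%s-%s", colnames(gt)[bad[, 1]],
                       colnames(gt)[bad[, 2]]), collapse = ", "))
  }
  d <- parts$SD / L
  diag(d) <- 0
  list(d = d, n_loci = L)
}

# summed |gi - gj| / 2 (SD) and shared-locus counts (L) via cross-products:
# |gi - gj| = gi + gj - 2*min(gi, gj), and with indicator matrices per
# dosage the pairwise sums decompose into crossprod terms
.ibsParts <- function(gt) {
  called <- !is.na(gt)
  g0 <- matrix(0, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g0[called] <- gt[called]
  L <- crossprod(called)
  # sum over shared loci of |gi - gj|:
  # = sum gi (called j) + sum gj (called i) - 2 * sum min(gi, gj)
  A <- crossprod(g0, called)          # (i,j): sum of g_i over loci called in j
  ge1 <- (g0 >= 1) & called           # indicator g >= 1
  ge2 <- (g0 >= 2) & called
  # min(gi, gj) = [gi>=1][gj>=1] + [gi>=2][gj>=2]
  M <- crossprod(ge1) + crossprod(ge2)
  SD <- (A + t(A) - 2 * M) / 2
  list(SD = SD, L = L)
}

#' Three-sample D3 statistic
#'
#' `D3 = (d_BC - d_AC) / (d_BC + d_AC)` for a trio in which A and B are the
#' sister pair and C the third population. Under clean divergence with no
#' post-divergence gene flow the two cross distances are exchangeable and
#' D3 = 0; gene flow between A and C shrinks `d_AC` and drives D3 positive,
#' gene flow between B and C drives it negative.
#'
#' @param dBC,dAC nonnegative genetic distances, not both 0.
#' @return D3 in \[-1, 1\]; `NA` when both distances are 0.
#' @examples
#' d3Statistic(0.11, 0.09)  # 0.1
#' @export
d3Statistic <- function(dBC, dAC) {
  ifelse(dBC == 0 & dAC == 0, NA_real_, (dBC - dAC) / (dBC + dAC))
}

#' D3Result: trio gene-flow inference
#'
#' Per-individual-triple D3 values for a population trio with the sister
#' pair (A, B) and third population C, a Z-based 95% confidence interval on
#' the mean, an empirical quantile interval, and (optionally) a
#' block-jackknife-over-loci interval, which accounts for the reuse of
#' individuals across triples and is labelled non-canonical.
#'
#' @slot popA,popB,popC population labels (A, B the sister pair).
#' @slot values per-triple D3.
#' @slot mean,sd,ciLower,ciUpper mean and Z-based 95% CI over triples.
#' @slot ciQuantile empirical 2.5%/97.5% quantiles of the triple values.
#' @slot ciJackknife block-jackknife-over-loci 95% CI on the mean (NA when
#'   not computed).
#' @slot nTriples,nSkipped triple counts (skipped: both distances zero).
#' @slot interpretation `"none"`, `"A-C gene flow"` or `"B-C gene flow"`
#'   from the sign of the Z interval.
#' @slot convention sign convention recorded for the record.
#' @export
setClass("D3Result", representation(
  popA = "character", popB = "character", popC = "character",
  values = "numeric", mean = "numeric", sd = "numeric",
  ciLower = "numeric", ciUpper = "numeric",
  ciQuantile = "numeric", ciJackknife = "numeric",
  nTriples = "integer", nSkipped = "integer",
  interpretation = "character", convention = "character"))

setMethod("show", "D3Result", function(object) {
  cat(sprintf("D3 trio: sisters (%s, %s), third %s\n",
              object@popA, object@popB, object@popC),
      sprintf("  mean D3 = %.4f, 95%% CI [%.4f, %.4f] over %d triples\n",
              object@mean, object@ciLower, object@ciUpper,
              object@nTriples),
      sprintf("  quantile CI [%.4f, %.4f]", object@ciQuantile[1],
              object@ciQuantile[2]),
      if (!anyNA(object@ciJackknife))
        sprintf(", locus-jackknife CI [%.4f, %.4f]",
                object@ciJackknife[1], object@ciJackknife[2]) else "",
      "\n", sprintf("  interpretation: %s\n", object@interpretation),
      sep = "")
})

#' D3 over all individual triples of a population trio
#'
#' Evaluates [d3Statistic()] for every triple (a in A, b in B, c in C)
#' using the individual IBS distances `d(b, c)` and `d(a, c)`, then
#' summarises: mean over triples, Z-based 95% CI
#' (`mean +/- 1.96 sd / sqrt(n)`), empirical quantile interval, and an
#' optional block-jackknife over loci. When the triple count exceeds
#' `maxTriples` a seeded subsample is used.
#'
#' Swapping the roles of A and B negates every triple's value. The
#' interpretation is read off the Z interval: positive and excluding 0
#' means A-C gene flow, negative means B-C gene flow, covering 0 means
#' none detected.
#'
#' @param g a [GenotypeMatrix] (typically the full filtered panel).
#' @param A,B,C population labels; (A, B) is the sister pair.
#' @param jackknifeBlocks number of contiguous locus blocks for the
#'   jackknife CI; 0 disables it.
#' @param maxTriples triple-enumeration budget before subsampling.
#' @param seed seed for the subsample (only used above the budget).
#' @return A [D3Result-class] object.
#' @export
d3Trio <- function(g, A, B, C, jackknifeBlocks = 20L,
                   maxTriples = 1e6, seed = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  pop <- populations(g)
  for (lbl in c(A, B, C))
    if (!any(pop == lbl)) stop("population is empty or unknown: ", lbl)
  gt <- genotypes(g)
  ia <- which(pop == A); ib <- which(pop == B); ic <- which(pop == C)
  dist <- ibsDistance(g)$d

  triples <- expand.grid(a = ia, b = ib, c = ic)
  if (nrow(triples) > maxTriples) {
    if (!is.null(seed)) set.seed(seed)
    triples <- triples[sample.int(nrow(triples), maxTriples), ]
  }
  dBC <- dist[cbind(triples$b, triples$c)]
  dAC <- dist[cbind(triples$a, triples$c)]
  vals <- d3Statistic(dBC, dAC)
  skipped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (n == 0L) stop("all triples degenerate (both distances zero)")
  m <- mean(vals)
  s <- if (n > 1L) sd(vals) else NA_real_
  half <- if (n > 1L) 1.96 * s / sqrt(n) else 0
  ci <- c(m - half, m + half)
  qq <- if (n > 1L) unname(quantile(vals, c(0.025, 0.975)))
        else c(m, m)

  jack <- c(NA_real_, NA_real_)
  if (jackknifeBlocks > 0L && nrow(gt) >= 2L) {
    jack <- .d3LocusJackknife(gt, triples, min(jackknifeBlocks, nrow(gt)))
  }

  interp <- "none"
  if (ci[1] > 0) interp <- sprintf("%s-%s gene flow", A, C)
  if (ci[2] < 0) interp <- sprintf("%s-%s gene flow", B, C)
  new("D3Result", popA = A, popB = B, popC = C, values = vals, mean = m,
      sd = s, ciLower = ci[1], ciUpper = ci[2], ciQuantile = qq,
      ciJackknife = jack, nTriples = as.integer(n),
      nSkipped = as.integer(skipped), interpretation = interp,
      convention = "D3 = (dBC - dAC)/(dBC + dAC); D3 > 0 implies A-C gene flow")
}

# leave-one-block-of-loci-out jackknife on the mean D3: per-block distance
# numerators/denominators are accumulated so each leave-out is cheap
.d3LocusJackknife <- function(gt, triples, nBlocks) {
  L <- nrow(gt)
  blocks <- cut(seq_len(L), nBlocks, labels = FALSE)
  sdParts <- lapply(seq_len(nBlocks), function(b)
    .ibsParts(gt[blocks == b, , drop = FALSE]))
  SDtot <- Reduce(`+`, lapply(sdParts, `[[`, "SD"))
  Ltot <- Reduce(`+`, lapply(sdParts, `[[`, "L"))
  ib <- cbind(triples$b, triples$c)
  ia <- cbind(triples$a, triples$c)
  means <- vapply(seq_len(nBlocks), function(b) {
    SD <- SDtot - sdParts[[b]]$SD
    Lc <- Ltot - sdParts[[b]]$L
    dBC <- SD[ib] / Lc[ib]
    dAC <- SD[ia] / Lc[ia]
    mean(d3Statistic(dBC, dAC), na.rm = TRUE)
  }, numeric(1))
  means <- means[is.finite(means)]
  J <- length(means)
  if (J < 2L) return(c(NA_real_, NA_real_))
  center <- mean(means)
  se <- sqrt((J - 1) / J * sum((means - center)^2))
  c(center - 1.96 * se, center + 1.96 * se)
}
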