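#' NeEstimate: LD-method effective population size
#'
#' Result container for [estimateNeLD()]. `ne`, `ciLower` and `ciUpper`
#' are positive reals or `Inf`; the estimate is infinite exactly when the
#' sampling-corrected mean squared correlation is not positive (drift too
#' weak to detect at this sample size), mirroring the "Infinite" entries
#' that LD-based estimators report for large populations.
#'
#' @slot population population label.
#' @slot mafCutoff minor-allele-frequency screen applied within the
#'   population.
#' @slot nLoci number of loci passing the MAF screen.
#' @slot nComparisons number of locus pairs used.
#' @slot r2Mean weighted mean squared dosage correlation.
#' @slot r2Expected sampling expectation of r-squared at this sample size.
#' @slot sHarmonic harmonic mean pairwise sample size.
#' @slot ne,ciLower,ciUpper point estimate and jackknife 95% CI.
#' @slot method metadata (formula variant, CI method).
#' @export
setClass("NeEstimate", representation(
  population = "character", mafCutoff = "numeric", nLoci = "integer",
  nComparisons = "numeric", r2Mean = "numeric", r2Expected = "numeric",
  sHarmonic = "numeric", ne = "numeric", ciLower = "numeric",
  ciUpper = "numeric", method = "list"))

setMethod("show", "NeEstimate", function(object) {
  fmtNe <- function(x) if (is.infinite(x)) "Infinite" else sprintf("%.1f", x)
  cat(sprintf("LD-method Ne for '%s' (MAF >= %.3g):\n",
              object@population, object@mafCutoff),
      sprintf("  Ne = %s  [%s, %s]\n", fmtNe(object@ne),
              fmtNe(object@ciLower), fmtNe(object@ciUpper)),
      sprintf("  mean r2 = %.5f (expectation %.5f), %d loci, %g pairs\n",
              object@r2Mean, object@r2Expected, object@nLoci,
              object@nComparisons), sep = "")
})

# Null sampling expectation of the squared Pearson dosage correlation for S
# diploids: exactly 1/(S-1) for independent loci. (The published
# 3.19/(S-1)^2 refinement is specific to the Burrows-composite r-squared as
# computed by the original software and over-corrects the plain Pearson
# form; see the methods vignette.)
.r2Expectation <- function(S) 1 / (S - 1)

.invertNe <- function(r2prime, S) {
  if (is.na(r2prime) || r2prime <= 0) return(Inf)
  if (S >= 30) {
    disc <- max(1 / 9 - 2.76 * r2prime, 0)
    (1 / 3 + sqrt(disc)) / (2 * r2prime)
  } else {
    disc <- max(0.308^2 - 2.08 * r2prime, 0)
    (0.308 + sqrt(disc)) / (2 * r2prime)
  }
}

#' LD-method effective population size
#'
#' Single-sample effective population size from linkage disequilibrium
#' among presumed-unlinked SNPs. Within the focal population, loci are
#' screened at `mafCutoff`; for every unordered locus pair the squared
#' Pearson correlation of dosages is computed over the samples called at
#' both loci (the Burrows composite equivalent for unphased diploid data),
#' and the mean r-squared is weighted by the pairwise sample size. The null
#' sampling expectation of the squared Pearson correlation is `1/(S - 1)`
#' (exact for independent loci); the drift inversion follows the
#' random-mating bias-corrected quadratic of Waples (2006) / Waples & Do,
#' with the small-sample variant below S = 30: with
#' `r2' = mean(r2) - E[r2]`,
#' \deqn{\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\, r^{2\prime}}}{2 r^{2\prime}}}
#' and `r2' <= 0` yields an infinite estimate. The 95% CI is a jackknife
#' on the mean r-squared transformed through the same inversion (larger
#' r-squared maps to smaller Ne, so the bounds swap): by default
#' delete-one-sample, which also captures the pedigree-level noise shared
#' across locus pairs; delete-one-locus is available as the cheaper
#' alternative but runs anticonservative.
#'
#' @param g a [GenotypeMatrix].
#' @param population label of the population to estimate.
#' @param mafCutoff within-population minor allele frequency screen
#'   (default 0.01; loci at or above the cutoff are kept).
#' @param ciMethod `"samples"` (delete-one-sample jackknife, default) or
#'   `"loci"` (delete-one-locus).
#' @return A [NeEstimate-class] object.
#' @export
estimateNeLD <- function(g, population, mafCutoff = 0.01,
                         ciMethod = c("samples", "loci")) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(is(g, "GenotypeMatrix"))
  pop <- populations(g)
  if (!population %in% pop) stop("unknown population: ", population)
  gt <- genotypes(g)[, pop == population, drop = FALSE]
  S0 <- ncol(gt)
  if (S0 < 10) warning("fewer than 10 samples; the estimate will be noisy")
  called <- !is.na(gt)
  n <- rowSums(called)
  p <- rowSums(gt, na.rm = TRUE) / (2 * pmax(n, 1L))
  maf <- pmin(p, 1 - p)
  keep <- n >= 2L & maf >= mafCutoff
  if (sum(keep) < 2L)
    stop("fewer than 2 loci pass the MAF screen in '", population, "'")
  gt <- gt[keep, , drop = FALSE]
  L <- nrow(gt)
  X <- t(gt)  # samples x loci

  # pairwise r2 and sample sizes; loci are columns
  pr <- .pairwiseR2(X)
  w <- pr$S
  ok <- !is.na(pr$r2) & w >= 2
  r2 <- pr$r2[ok]; w <- w[ok]
  li <- pr$i[ok]; lj <- pr$j[ok]
  if (!length(r2)) stop("no usable locus pairs")
  r2Mean <- sum(w * r2) / sum(w)
  Sharm <- length(w) / sum(1 / w)
  Er2 <- .r2Expectation(Sharm)
  ne <- .invertNe(r2Mean - Er2, Sharm)

  if (ciMethod == "samples") {
    # delete-one-sample jackknife: recompute the weighted mean r2 without
    # each individual (the constant shift in the sampling expectation at
    # S - 1 does not affect the spread)
    S <- nrow(X)
    thetas <- vapply(seq_len(S), function(i) {
      pri <- .pairwiseR2(X[-i, , drop = FALSE])
      oki <- !is.na(pri$r2) & pri$S >= 2
      sum(pri$S[oki] * pri$r2[oki]) / sum(pri$S[oki])
    }, numeric(1))
  } else {
    # delete-one-locus jackknife via per-locus pair-sum accumulation
    totW <- sum(w); totWR <- sum(w * r2)
    accum <- function(x) {
      out <- numeric(L)
      a <- rowsum(x, li); out[as.integer(rownames(a))] <- a
      b <- rowsum(x, lj)
      idx <- as.integer(rownames(b))
      out[idx] <- out[idx] + b
      out
    }
    dW <- totW - accum(w)
    dWR <- totWR - accum(w * r2)
    thetas <- ifelse(dW > 0, dWR / dW, NA_real_)
  }
  thetas <- thetas[!is.na(thetas)]
  J <- length(thetas)
  seJack <- sqrt((J - 1) / J * sum((thetas - mean(thetas))^2))
  r2Lo <- r2Mean - 1.96 * seJack
  r2Hi <- r2Mean + 1.96 * seJack
  new("NeEstimate", population = population, mafCutoff = mafCutoff,
      nLoci = L, nComparisons = as.numeric(length(r2)),
      r2Mean = r2Mean, r2Expected = Er2, sHarmonic = Sharm,
      ne = ne,
      ciLower = .invertNe(r2Hi - Er2, Sharm),
      ciUpper = .invertNe(r2Lo - Er2, Sharm),
      method = list(expectation = "1/(S-1) Pearson null; Waples random-mating inversion",
                    ci = sprintf("delete-one-%s jackknife, 95%%",
                                 if (ciMethod == "samples") "sample"
                                 else "locus"),
                    weighting = "pairwise sample size"))
}

# squared Pearson correlation for all locus pairs with pairwise-complete
# samples; returns parallel vectors i, j, r2, S
.pairwiseR2 <- function(X) {
  L <- ncol(X)
  idx <- which(upper.tri(diag(L)), arr.ind = TRUE)
  if (!anyNA(X)) {
    r <- suppressWarnings(cor(X))  # zero-variance columns give NA pairs
    S <- matrix(nrow(X), L, L)
  } else {
    r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
    S <- crossprod(!is.na(X))
  }
  list(i = idx[, 1], j = idx[, 2], r2 = r[idx]^2, S = S[idx])
}
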