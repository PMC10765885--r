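test_that("PCA separates two clusters of identical samples on PC1", {
  gt <- cbind(a1 = rep(0L, 20), a2 = rep(0L, 20),
              b1 = rep(2L, 20), b2 = rep(2L, 20))
  p <- pcaAlleleFreq(makeGM(gt, c("A", "A", "B", "B")))
  expect_equal(p$explained[1], 1)
  expect_gt(abs(p$scores[1, 1] - p$scores[3, 1]), 1)
  expect_equal(p$scores[1, 1], p$scores[2, 1])
})

test_that("explained fractions are non-increasing, sum to <= 1, scores orthogonal", {
  g <- hweGM(80, 15, pops = rep(c("A", "B", "C"), each = 5),
             missing = 0.1, seed = 21)
  p <- pcaAlleleFreq(g, nComponents = 6)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  cp <- crossprod(p$scores)
  offdiag <- cp[upper.tri(cp)]
  expect_true(all(abs(offdiag) < 1e-6 * max(diag(cp))))
  # sign convention: first sample nonnegative everywhere
  expect_true(all(p$scores[1, ] >= 0))
})

test_that("missing dosages are imputed with the population mean", {
  gt <- rbind(c(0L, 2L, NA, 2L, 2L))
  g <- makeGM(gt, c("A", "A", "B", "B", "B"))
  # population B mean at the locus is 2 -> imputed cell has zero variance
  # within B; the locus stays informative between populations
  p <- pcaAlleleFreq(g, nComponents = 1)
  expect_equal(p$scores[3, 1], p$scores[4, 1])
})

test_that("PCA clusters simulated diverged populations (positive silhouette)", {
  sim <- simulateGenotypes(threePopModel(N = 500, T2 = 300, T1 = 900),
                           c(A = 10, B = 10, C = 10), 800, seed = 31)
  p <- pcaAlleleFreq(sim$genotypes, nComponents = 2)
  sil <- cluster::silhouette(
    as.integer(factor(populations(sim$genotypes))),
    dist(p$scores))
  bycluster <- tapply(sil[, "sil_width"], sil[, "cluster"], mean)
  expect_true(all(bycluster > 0))
})

test_that("neighbor joining reproduces three-point closed-form branch lengths", {
  d <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- ape::read.tree(text = njDendrogram(d))
  lens <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                          tree$edge[, 2])], tree$tip.label)
  expect_equal(unname(lens["A"]), (.1 + .2 - .3) / 2, tolerance = 1e-9)
  expect_equal(unname(lens["B"]), (.1 + .3 - .2) / 2)
  expect_equal(unname(lens["C"]), (.2 + .3 - .1) / 2)
})

test_that("NJ recovers additive trees and clamps negatives sensibly", {
  # additive 4-taxon distances from a known tree recover its topology
  for (seed in 1:5) {
    set.seed(seed)
    nt <- sample(4:8, 1)
    truth <- ape::rtree(nt, rooted = FALSE)
    d <- cophenetic(truth)
    est <- ape::read.tree(text = njDendrogram(d))
    expect_equal(ape::dist.topo(ape::unroot(truth), est), 0,
                 ignore_attr = TRUE)
    expect_true(all(est$edge.length >= 0))
  }

  # equal distances: all external branches equal
  dEq <- matrix(0.2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(dEq) <- 0
  tr <- ape::read.tree(text = njDendrogram(dEq))
  ext <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(ext, rep(0.1, 4))

  expect_error(njDendrogram(matrix(0, 2, 2)), "at least 3")
})
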