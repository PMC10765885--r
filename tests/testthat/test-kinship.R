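test_that("KING-robust phi matches hand counts and identities", {
  # duplicate samples sharing heterozygous loci -> phi = 0.5
  dup <- makeGM(cbind(c(1L, 0L, 1L, 2L), c(1L, 0L, 1L, 2L)), rep("A", 2))
  expect_equal(kingKinship(dup)$phi, 0.5)
  expect_identical(kingKinship(dup)$degree, "duplicate")

  # hand count: both-het 1, opposite-hom 0, het counts 2 and 2 -> 0.25
  g <- makeGM(cbind(c(1L, 1L, 0L, 2L), c(1L, 0L, 1L, 2L)), rep("A", 2))
  k <- kingKinship(g)
  expect_equal(k$phi, 0.25)
  expect_identical(k$degree, "first")
  expect_identical(k$n_loci, 4)

  # opposite homozygotes at every locus -> negative phi... but with no
  # heterozygous locus the denominator is zero and phi is undefined
  opp <- makeGM(cbind(c(0L, 0L, 1L), c(2L, 2L, 1L)), rep("A", 2))
  expect_lt(kingKinship(opp)$phi, 0)

  allopp <- makeGM(cbind(c(0L, 0L), c(2L, 2L)), rep("A", 2))
  k0 <- kingKinship(allopp)
  expect_true(is.na(k0$phi))
  expect_true(k0$undefined)
  expect_identical(k0$degree, "unrelated")
})

test_that("phi is invariant to allele-label swaps and ignores pairwise-missing loci", {
  set.seed(7)
  g <- hweGM(60, 8, missing = 0.1)
  k1 <- kingKinship(g)
  gt <- genotypes(g)
  flip <- sample(nrow(gt), 25)
  gt[flip, ] <- 2L - gt[flip, ]
  k2 <- kingKinship(makeGM(gt, populations(g)))
  expect_equal(k1$phi, k2$phi)
  expect_identical(k1$n_loci, k2$n_loci)
})

test_that("greedy pruning removes one per pair, hubs first, ties by id", {
  # isolated pair: lexicographic tie-break picks 'a'
  pair <- data.frame(sample_i = "a", sample_j = "b", n_loci = 10,
                     phi = 0.3, degree = "first", undefined = FALSE)
  g <- makeGM(matrix(1L, 3, 2, dimnames = list(NULL, c("a", "b"))),
              rep("P", 2))
  out <- pruneRelatives(g, pair)
  expect_identical(out$removed, "a")
  expect_identical(colnames(out$genotypes), "b")

  # star: hub A related to B, C, D -> only A removed
  star <- data.frame(sample_i = "A", sample_j = c("B", "C", "D"),
                     n_loci = 10, phi = 0.2, degree = "first",
                     undefined = FALSE)
  g4 <- makeGM(matrix(1L, 3, 4, dimnames = list(NULL, LETTERS[1:4])),
               rep("P", 4))
  out4 <- pruneRelatives(g4, star)
  expect_identical(out4$removed, "A")
  expect_identical(ncol(out4$genotypes), 3L)
})

test_that("no pair above the cutoff survives pruning (random panels)", {
  for (seed in 1:3) {
    set.seed(seed)
    base <- hweGM(80, 12, seed = seed)
    gt <- genotypes(base)
    # inject two related pairs by near-duplication
    for (j in c(2L, 7L)) {
      gt[, j] <- gt[, j - 1L]
      mut <- sample(80, 8)
      gt[mut, j] <- sample(0:2, 8, TRUE)
    }
    g <- makeGM(gt, populations(base))
    k <- kingKinship(g)
    pruned <- pruneRelatives(g, k)
    kk <- kingKinship(pruned$genotypes)
    expect_true(all(is.na(kk$phi) | kk$phi <= 0.0884))
  }
})

test_that("a panel of 190 with 8 disjoint related pairs loses exactly 8", {
  set.seed(11)
  base <- hweGM(2000, 190, pops = rep("P", 190))
  gt <- genotypes(base)
  pairCols <- seq(2, 16, by = 2)  # 8 disjoint pairs (1,2), (3,4), ...
  for (j in pairCols) {
    gt[, j] <- gt[, j - 1L]
    mut <- sample(2000, 150)        # slight divergence, related 1st degree
    gt[mut, j] <- rbinom(150, 2L, 0.5)
  }
  g <- makeGM(gt, populations(base))
  k <- kingKinship(g)
  out <- pruneRelatives(g, k)
  expect_identical(length(out$removed), 8L)
  expect_identical(ncol(out$genotypes), 182L)
  kk <- kingKinship(out$genotypes)
  expect_true(all(is.na(kk$phi) | kk$phi <= 0.0884))
})
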