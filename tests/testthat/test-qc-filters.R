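test_that("locus filters apply the documented rules and boundaries", {
  # MAC: pooled [0,0,0,1] has minor count 1 < 3 -> removed
  g <- makeGM(rbind(c(0L, 0L, 0L, 1L)), rep("A", 4))
  out <- filterLoci(g, qcConfig(minCallRate = 0))
  expect_identical(nLoci(out$genotypes), 0L)
  expect_identical(out$report$mac, 1L)

  # per-population call rate, boundary inclusive at the cutoff:
  # locus 1 called in 4/5 of pop B (= 0.8, retained), locus 2 in 3/5
  gt <- rbind(c(1L, 1L, 2L, 0L, 1L, 1L, 0L, 1L, 1L, NA),
              c(1L, 1L, 2L, 0L, 1L, 1L, 0L, 1L, NA, NA))
  g2 <- makeGM(gt, rep(c("A", "B"), each = 5))
  out2 <- filterLoci(g2, qcConfig(minMAC = 0L))
  expect_identical(rownames(out2$genotypes), "L001")
  expect_identical(out2$report$call_rate, 1L)

  # sample call rate is a strict "<": exactly 70% is retained
  gt3 <- matrix(1L, 10, 3)
  gt3[1:4, 1] <- NA  # 60% called -> removed
  gt3[1:3, 2] <- NA  # 70% called -> retained
  g3 <- makeGM(gt3, rep("A", 3))
  out3 <- filterSamples(g3)
  expect_identical(out3$removed, "s001")
  expect_identical(ncol(out3$genotypes), 2L)

  # all samples below the cutoff is an error
  g4 <- makeGM(matrix(NA_integer_, 10, 2,
                      dimnames = list(NULL, c("a", "b"))), rep("A", 2))
  expect_error(filterSamples(g4), "all samples")
})

test_that("depth rule matches a brute-force mean + 2 SD computation", {
  depths <- c(rep(10, 12), 100)
  g <- makeGM(matrix(1L, 13, 6), rep("A", 6), meanDepth = depths)
  lim <- mean(depths) +
    2 * sqrt(sum((depths - mean(depths))^2) / (length(depths) - 1))
  expect_identical(which(depths > lim), 13L)  # the brute-force oracle
  out <- filterLoci(g, qcConfig(minCallRate = 0, minMAC = 0L))
  expect_identical(rownames(out$genotypes), sprintf("L%03d", 1:12))
  expect_identical(out$report$depth, 1L)
})

test_that("first-SNP-per-locus keeps input order within groups", {
  gt <- matrix(c(0L, 1L, 2L, 1L), 4, 6)
  g <- makeGM(gt, rep("A", 6),
              locusGroup = c("tag1", "tag1", "tag2", "tag1"))
  out <- filterLoci(g, qcConfig(minCallRate = 0, minMAC = 0L))
  expect_identical(rownames(out$genotypes), c("L001", "L003"))
  expect_identical(out$report$first_snp, 2L)
})

test_that("filters are idempotent and call-rate/MAC rules commute", {
  for (seed in 1:4) {
    g <- hweGM(40, 20, pops = rep(c("A", "B"), each = 10),
               missing = 0.15, seed = seed)
    cfg <- qcConfig(minCallRate = 0.8, minMAC = 3L)
    once <- filterLoci(g, cfg)$genotypes
    twice <- filterLoci(once, cfg)$genotypes
    expect_identical(genotypes(once), genotypes(twice))

    s1 <- filterSamples(g, qcConfig(minSampleCallRate = 0.8))$genotypes
    s2 <- filterSamples(s1, qcConfig(minSampleCallRate = 0.8))$genotypes
    expect_identical(colnames(s1), colnames(s2))

    # order independence of the two locus rules
    onlyCR <- qcConfig(minCallRate = 0.8, minMAC = 0L, firstSNPOnly = FALSE)
    onlyMAC <- qcConfig(minCallRate = 0, minMAC = 3L, firstSNPOnly = FALSE)
    ab <- filterLoci(filterLoci(g, onlyCR)$genotypes, onlyMAC)$genotypes
    ba <- filterLoci(filterLoci(g, onlyMAC)$genotypes, onlyCR)$genotypes
    expect_identical(rownames(ab), rownames(ba))
  }
})

test_that("a fixture with exactly two low-call samples drops 190 to 188", {
  set.seed(99)
  g <- hweGM(50, 190, pops = rep(c("P1", "P2"), 95))
  gt <- genotypes(g)
  gt[1:20, 5] <- NA   # 60% called
  gt[1:18, 120] <- NA # 64% called
  g <- makeGM(gt, populations(g))
  out <- filterSamples(g)
  expect_identical(out$report$samples_removed, 2L)
  expect_identical(ncol(out$genotypes), 188L)
})
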