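test_that("full-sample projection places integer mass at observed counts", {
  # 2 pops x 2 diploids, alt counts (1, 0), projection = full sample
  g <- makeGM(rbind(c(1L, 0L, 0L, 0L)), c("A", "A", "B", "B"))
  s <- jointSFS(g, c("A", "B"), c(4, 4), folded = FALSE)
  expect_equal(s@counts[2, 1], 1)
  expect_equal(sum(s@counts), 1)
  expect_identical(s@dropped, 0L)
})

test_that("projection masses are the closed-form hypergeometric probabilities", {
  # 3 alt among 8 alleles projected to 4 draws: choose(3,k) choose(5,4-k) / choose(8,4)
  g <- makeGM(rbind(c(2L, 1L, 0L, 0L, 0L, 0L)),
              c("A", "A", "A", "A", "B", "B"))
  s <- jointSFS(g, c("A", "B"), c(4, 4), folded = FALSE)
  oracle <- choose(3, 0:4) * choose(5, 4 - (0:4)) / choose(8, 4)
  expect_equal(unname(s@counts[, 1]), oracle)
  # every SNP's projected mass sums to 1 before masking
  expect_equal(sum(s@counts), 1)
})

test_that("sites with too few called alleles are dropped and counted", {
  gt <- rbind(c(1L, NA, 0L, 0L),  # pop A has 2 called alleles < proj 4
              c(1L, 1L, 0L, 0L))
  g <- makeGM(gt, c("A", "A", "B", "B"))
  s <- jointSFS(g, c("A", "B"), c(4, 4), folded = FALSE)
  expect_identical(s@dropped, 1L)
  expect_equal(sum(s@counts), 1)
  expect_error(jointSFS(g, c("A", "B"), c(6, 4)), "projection exceeds")
})

test_that("folding is canonical and an involution-quotient", {
  set.seed(81)
  g <- hweGM(40, 12, pops = rep(c("A", "B"), each = 6), missing = 0.1)
  unf <- jointSFS(g, c("A", "B"), c(8, 8), folded = FALSE)
  fld <- foldSFS(unf)
  expect_identical(foldSFS(fld), fld)                 # idempotent
  expect_equal(sum(unf@counts), sum(fld@counts))      # mass conserved
  # each configuration and its complement share a cell after folding
  grid <- as.matrix(expand.grid(0:8, 0:8))
  for (r in sample(nrow(grid), 15)) {
    k <- grid[r, ]; comp <- c(8, 8) - k
    canon <- if (isTRUE(all(k == comp)) ||
                 k[which(k != comp)[1]] < comp[which(k != comp)[1]]) k
             else comp
    other <- c(8, 8) - canon
    if (!all(canon == other))
      expect_equal(fld@counts[other[1] + 1, other[2] + 1], 0)
  }
  # monomorphic corner masked
  expect_true(fld@mask[1, 1])
  expect_true(unf@mask[9, 9])
})

test_that("total mass plus dropped sites accounts for every input SNP", {
  set.seed(82)
  g <- hweGM(60, 10, pops = rep(c("A", "B"), each = 5), missing = 0.25)
  s <- jointSFS(g, c("A", "B"), c(8, 8), folded = TRUE)
  polymorphicMass <- sfsTotal(s)
  maskedMass <- sum(s@counts[s@mask])
  expect_equal(polymorphicMass + maskedMass + s@dropped, 60)
})

test_that("the SNP bootstrap is seeded, reproducible and recentred", {
  set.seed(83)
  g <- hweGM(50, 12, pops = rep(c("A", "B"), each = 6))
  b1 <- bootstrapSFS(g, c("A", "B"), c(10, 10), reps = 3, seed = 5)
  b2 <- bootstrapSFS(g, c("A", "B"), c(10, 10), reps = 3, seed = 5)
  for (i in 1:3) expect_equal(b1[[i]]@counts, b2[[i]]@counts)

  # resampling identical columns reproduces the observed spectrum exactly
  mono <- makeGM(matrix(rep(c(1L, 0L, 1L, 2L), 6), 6, 4, byrow = TRUE),
                 c("A", "A", "B", "B"))
  obs <- jointSFS(mono, c("A", "B"), c(4, 4))
  rep1 <- bootstrapSFS(mono, c("A", "B"), c(4, 4), reps = 1, seed = 1)[[1]]
  expect_equal(rep1@counts, obs@counts)

  # bootstrap totals are centred on the observed total
  tot <- vapply(bootstrapSFS(g, c("A", "B"), c(10, 10), reps = 30,
                             seed = 6), sfsTotal, numeric(1))
  expect_lt(abs(mean(tot) - sfsTotal(jointSFS(g, c("A", "B"), c(10, 10)))),
            3 * sd(tot) / sqrt(length(tot)))
})

test_that("dadi-style text serialization round-trips", {
  set.seed(84)
  g <- hweGM(30, 9, pops = rep(c("A", "B", "C"), each = 3))
  s <- jointSFS(g, c("A", "B", "C"), c(4, 4, 4), folded = TRUE)
  td <- withr::local_tempdir()
  writeSFS(s, file.path(td, "x.fs"))
  r <- readSFS(file.path(td, "x.fs"))
  expect_equal(r@counts, s@counts)
  expect_identical(r@mask, s@mask)
  expect_identical(r@folded, TRUE)
  expect_identical(r@populations, c("A", "B", "C"))
})

test_that("goodness of fit is maximal for the spectrum against itself", {
  set.seed(85)
  g <- hweGM(40, 8, pops = rep(c("A", "B"), each = 4))
  s <- jointSFS(g, c("A", "B"), c(6, 6))
  other <- jointSFS(g[sample(40, 30), ], c("A", "B"), c(6, 6))
  expect_gte(sfsLogLik(s, s) / sfsTotal(s),
             sfsLogLik(s, other) / sfsTotal(s))
})

test_that("calendar conversions follow the stated life history", {
  expect_equal(yearsToGenerations(588), 294)
  expect_equal(yearsToGenerations(896), 448)
  expect_equal(yearsToGenerations(0), 0)
  expect_equal(yearsToGenerations(100, generationTime = 4), 25)
  expect_equal(driftFixationGenerations(1076), 4304)
  expect_equal(driftFixationGenerations(1), 4)
  expect_equal(driftFixationGenerations(500), 2000)
  expect_error(driftFixationGenerations(0))
})
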