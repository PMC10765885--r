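test_that("IBS distance matches hand counts and its bounds", {
  # identical -> 0; opposite homozygotes everywhere -> 1
  same <- makeGM(cbind(c(0L, 1L, 2L), c(0L, 1L, 2L)), rep("P", 2))
  expect_equal(ibsDistance(same)$d[1, 2], 0)
  opp <- makeGM(cbind(c(0L, 2L), c(2L, 0L)), rep("P", 2))
  expect_equal(ibsDistance(opp)$d[1, 2], 1)

  # per-locus sharing 0 and 1 -> d = 0.5
  g <- makeGM(cbind(c(0L, 2L), c(2L, 2L)), rep("P", 2))
  expect_equal(ibsDistance(g)$d[1, 2], 0.5)

  # het vs hom shares half
  h <- makeGM(cbind(c(1L), c(0L)), rep("P", 2))
  expect_equal(ibsDistance(h)$d[1, 2], 0.5)

  # missing loci are excluded pairwise; an empty intersection errors
  m <- makeGM(cbind(c(1L, NA), c(NA, 1L)), rep("P", 2))
  expect_error(ibsDistance(m), "no shared called loci")
})

test_that("the D3 ratio evaluates exactly and at its boundaries", {
  expect_equal(d3Statistic(0.11, 0.09), 0.1)
  expect_equal(d3Statistic(0.2, 0.2), 0)
  expect_equal(d3Statistic(0, 0.3), -1)
  expect_equal(d3Statistic(0.3, 0), 1)
  expect_true(is.na(d3Statistic(0, 0)))
})

test_that("trio D3 is antisymmetric in the sister pair and scale invariant", {
  sim <- simulateGenotypes(threePopModel(N = 300, T2 = 100, T1 = 400),
                           c(A = 5, B = 5, C = 5), 400, seed = 71)
  g <- sim$genotypes
  ab <- d3Trio(g, "A", "B", "C", jackknifeBlocks = 0)
  ba <- d3Trio(g, "B", "A", "C", jackknifeBlocks = 0)
  expect_equal(sort(ba@values), sort(-ab@values))
  expect_equal(ba@mean, -ab@mean)
  expect_true(all(abs(ab@values) <= 1))

  # rescaling all distances leaves D3 untouched (ratio statistic)
  d <- ibsDistance(g)$d
  expect_equal(d3Statistic(3 * d[2, 11], 3 * d[1, 11]),
               d3Statistic(d[2, 11], d[1, 11]))
})

test_that("degenerate trios are handled explicitly", {
  g1 <- makeGM(cbind(a = c(0L, 1L), b = c(2L, 1L), c = c(0L, 0L)),
               c("A", "B", "C"))
  r <- d3Trio(g1, "A", "B", "C", jackknifeBlocks = 0)
  expect_identical(r@nTriples, 1L)
  expect_equal(r@ciLower, r@mean)
  expect_equal(r@ciUpper, r@mean)

  dupes <- makeGM(cbind(a = c(0L, 1L), b = c(0L, 1L), c = c(0L, 1L)),
                  c("A", "B", "C"))
  expect_error(d3Trio(dupes, "A", "B", "C"), "degenerate")
  expect_error(d3Trio(g1, "A", "B", "nope"), "empty or unknown")
})

test_that("a seeded subsample keeps the triple budget and reproduces", {
  sim <- simulateGenotypes(threePopModel(N = 300, T2 = 100, T1 = 400),
                           c(A = 6, B = 6, C = 6), 300, seed = 72)
  r1 <- d3Trio(sim$genotypes, "A", "B", "C", maxTriples = 50,
               seed = 9, jackknifeBlocks = 0)
  r2 <- d3Trio(sim$genotypes, "A", "B", "C", maxTriples = 50,
               seed = 9, jackknifeBlocks = 0)
  expect_identical(r1@nTriples, 50L)
  expect_equal(r1@values, r2@values)
})

test_that("directional gene flow drives the trio mean in the predicted direction", {
  # strong third->sister-A migration shortens d(A, C): D3 > 0 with the
  # locus-jackknife interval excluding zero
  sim <- simulateGenotypes(threePopModel(N = 1000, migCA = 1e-2),
                           c(A = 10, B = 10, C = 10), 800, seed = 73)
  r <- d3Trio(sim$genotypes, "A", "B", "C")
  expect_gt(r@mean, 0)
  expect_gt(r@ciJackknife[1], 0)
  expect_match(r@interpretation, "A-C gene flow")
})
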