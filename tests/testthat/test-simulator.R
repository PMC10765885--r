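test_that("fitted-model presets encode the published parameter sets", {
  fast <- demographicPreset("fast")
  expect_equal(min(fast@merges$time), 294)   # T2 = 587.5 yr / 2
  expect_equal(max(fast@merges$time), 1892)  # T1 = 3783.8 yr / 2
  expect_equal(fast@mu, 6.6e-8)
  # the fitted Foskett -> Deep rate is exactly zero in both models
  expect_false(any(fast@migration$from == "Foskett" &
                   fast@migration$to == "Deep"))
  fs <- fast@sizeEpochs[fast@sizeEpochs$pop == "Foskett", ]
  expect_equal(fs$n0, 1076); expect_equal(fs$n1, 114)
  expect_identical(fs$type, "exponential")

  slow <- demographicPreset("slow")
  expect_equal(slow@mu, 1.2e-8)
  expect_equal(min(slow@merges$time), 448)   # 896 yr / 2
  expect_error(demographicPreset("nope"))
})

test_that("model validation rejects inconsistent histories", {
  expect_error(demographicModel("p",
    data.frame(pop = "p", t0 = 0, t1 = Inf, n0 = -5, n1 = -5,
               type = "constant")), "sizes")
  # two roots
  expect_error(demographicModel(c("a", "b"),
    data.frame(pop = c("a", "b"), t0 = 0, t1 = Inf, n0 = 10, n1 = 10,
               type = "constant")), "exactly one population")
  expect_error(demographicModel("p",
    data.frame(pop = "p", t0 = 0, t1 = Inf, n0 = 10, n1 = 10,
               type = "constant"),
    migration = data.frame(t0 = 0, t1 = 10, from = "p", to = "p",
                           rate = 1.5)), "migration")
})

test_that("identical seeds give bit-identical datasets", {
  m <- threePopModel(N = 200, T2 = 50, T1 = 150)
  s1 <- simulateGenotypes(m, c(A = 5, B = 5, C = 5), 200, seed = 91,
                          gbsNoise = TRUE)
  s2 <- simulateGenotypes(m, c(A = 5, B = 5, C = 5), 200, seed = 91,
                          gbsNoise = TRUE)
  expect_identical(genotypes(s1$genotypes), genotypes(s2$genotypes))
  expect_identical(s1$truth$tmrca, s2$truth$tmrca)
  s3 <- simulateGenotypes(m, c(A = 5, B = 5, C = 5), 200, seed = 92)
  expect_false(identical(s1$truth$tmrca, s3$truth$tmrca))
})

test_that("pairwise coalescence times match the discrete Wright-Fisher expectation", {
  m <- demographicModel("p", data.frame(pop = "p", t0 = 0, t1 = Inf,
                                        n0 = 100, n1 = 100,
                                        type = "constant"))
  s <- simulateGenotypes(m, c(p = 1), 6000, seed = 93)
  tm <- s$truth$tmrca
  expect_lt(abs(mean(tm) - 200), 3 * sd(tm) / sqrt(length(tm)))
  # 4 haploids: E[TMRCA] = 2 * 2N * (1 - 1/4)
  s4 <- simulateGenotypes(m, c(p = 2), 6000, seed = 94)
  tm4 <- s4$truth$tmrca
  expect_lt(abs(mean(tm4) - 300), 3 * sd(tm4) / sqrt(length(tm4)))
})

test_that("pairwise diversity approximates 4 N mu in the low-mutation regime", {
  m <- demographicModel("p", data.frame(pop = "p", t0 = 0, t1 = Inf,
                                        n0 = 100, n1 = 100,
                                        type = "constant"), mu = 1e-4)
  s <- simulateGenotypes(m, c(p = 1), 8000, seed = 95,
                         mutationModel = "poisson",
                         dropMonomorphic = FALSE)
  het <- genotypes(s$genotypes) == 1L
  expect_lt(abs(mean(het) - 4 * 100 * 1e-4),
            3 * sd(het) / sqrt(length(het)))
})

test_that("GBS noise adds depth metadata and the requested missingness", {
  g <- hweGM(300, 20, seed = 96)
  noisy <- addGBSNoise(g, list(dropout = 0.2, depthMean = 50))
  expect_false(is.null(meanDepth(noisy)))
  expect_gt(mean(meanDepth(noisy)), 25)
  miss <- mean(is.na(genotypes(noisy)))
  expect_lt(abs(miss - 0.2), 0.03)
})

test_that("the one-mutation model always emits segregating biallelic sites", {
  s <- simulateGenotypes(threePopModel(N = 150, T2 = 40, T1 = 120),
                         c(A = 4, B = 4, C = 4), 300, seed = 97)
  gt <- genotypes(s$genotypes)
  expect_identical(nrow(gt), 300L)
  mono <- apply(gt, 1, function(x) length(unique(x)) == 1L &&
                                   x[1] %in% c(0L, 2L))
  expect_false(any(mono))
  expect_true(all(s$truth$n_mutations == 1L))
})

test_that("Wright-Fisher forward simulation drifts at the expected rate", {
  # variance of allele frequency change over t generations ~ p0 q0 t / 2N
  p1 <- replicate(40, {
    wf <- simulateWrightFisher(50, 50, 50, nGenerations = 10,
                               initFreqRange = c(0.5, 0.5))
    mean(colMeans(t(genotypes(wf))) / 2)
  })
  expect_lt(abs(mean(p1) - 0.5), 0.05)
  wf <- simulateWrightFisher(30, 100, 10, seed = 98)
  expect_identical(dim(genotypes(wf)), c(100L, 10L))
})
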