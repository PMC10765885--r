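#' DemographicModel: event-based multi-population history
#'
#' Describes a structured demographic history in backward time, in
#' generations. `sizeEpochs` gives per-population diploid size
#' trajectories (`type` one of `"constant"`, `"linear"`, `"exponential"`;
#' `n0` the size at the recent end `t0`, `n1` at the ancient end `t1`).
#' `merges` are population-split events read backward: at `time`, every
#' lineage in `from` moves into `to`. `migration` rows carry
#' **forward-time** rates: `rate` is the fraction of population `to`
#' replaced by migrants from `from` each generation, which backward in
#' time is the probability that a lineage currently in `to` jumps to
#' `from`. `splitFractions` records the forward split proportions of the
#' fitted model; backward they determine only the daughter deme sizes, so
#' they are carried as metadata.
#'
#' @slot name model label.
#' @slot populations all deme labels (sampled and ancestral).
#' @slot sizeEpochs data.frame (pop, t0, t1, n0, n1, type).
#' @slot merges data.frame (time, from, to), times strictly positive.
#' @slot migration data.frame (t0, t1, from, to, rate), forward rates.
#' @slot splitFractions named numeric, forward split proportions.
#' @slot mu per-base per-generation mutation rate.
#' @slot generationTime generation time in years.
#' @export
setClass("DemographicModel", representation(
  name = "character", populations = "character",
  sizeEpochs = "data.frame", merges = "data.frame",
  migration = "data.frame", splitFractions = "numeric",
  mu = "numeric", generationTime = "numeric"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  se <- object@sizeEpochs
  need <- c("pop", "t0", "t1", "n0", "n1", "type")
  if (!all(need %in% names(se)))
    return("sizeEpochs needs columns pop, t0, t1, n0, n1, type")
  if (!all(se$pop %in% object@populations))
    msg <- c(msg, "sizeEpochs references unknown populations")
  if (any(se$n0 <= 0 | se$n1 <= 0)) msg <- c(msg, "sizes must be > 0")
  if (any(se$t0 < 0 | se$t1 < se$t0)) msg <- c(msg, "epoch times must be ordered")
  if (nrow(object@merges)) {
    if (any(object@merges$time <= 0))
      msg <- c(msg, "merge times must be > 0")
    if (!all(c(object@merges$from, object@merges$to) %in%
             object@populations))
      msg <- c(msg, "merges reference unknown populations")
  }
  if (nrow(object@migration)) {
    if (any(object@migration$rate < 0 | object@migration$rate >= 1))
      msg <- c(msg, "migration rates must lie in [0, 1)")
    if (!all(c(object@migration$from, object@migration$to) %in%
             object@populations))
      msg <- c(msg, "migration references unknown populations")
  }
  # single root: exactly one population whose epochs extend to infinity
  roots <- unique(se$pop[is.infinite(se$t1)])
  if (length(roots) != 1L)
    msg <- c(msg, "exactly one population must extend to infinite time")
  if (anyDuplicated(object@populations))
    msg <- c(msg, "population labels must be unique")
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (object@generationTime <= 0)
    msg <- c(msg, "generationTime must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel '%s': %d demes, mu = %g, generation = %g yr\n",
              object@name, length(object@populations), object@mu,
              object@generationTime))
  if (nrow(object@merges))
    for (i in seq_len(nrow(object@merges)))
      cat(sprintf("  t=%g: %s -> %s\n", object@merges$time[i],
                  object@merges$from[i], object@merges$to[i]))
  if (nrow(object@migration))
    cat(sprintf("  %d forward migration band(s)\n", nrow(object@migration)))
})

#' Construct a demographic model
#'
#' @param populations character vector of deme labels.
#' @param sizeEpochs data.frame with columns `pop`, `t0`, `t1`, `n0`,
#'   `n1`, `type` (see [DemographicModel-class]).
#' @param merges data.frame with columns `time`, `from`, `to`; may be
#'   empty for a single population.
#' @param migration data.frame with columns `t0`, `t1`, `from`, `to`,
#'   `rate` (forward-time rates); may be empty.
#' @param splitFractions named numeric metadata.
#' @param mu mutation rate per bp per generation.
#' @param generationTime years per generation.
#' @param name model label.
#' @return A validated [DemographicModel-class].
#' @export
demographicModel <- function(populations, sizeEpochs,
                             merges = data.frame(), migration = data.frame(),
                             splitFractions = numeric(), mu = 6.6e-8,
                             generationTime = 2, name = "custom") {
  if (!nrow(merges))
    merges <- data.frame(time = numeric(), from = character(),
                         to = character())
  if (!nrow(migration))
    migration <- data.frame(t0 = numeric(), t1 = numeric(),
                            from = character(), to = character(),
                            rate = numeric())
  new("DemographicModel", name = name,
      populations = as.character(populations),
      sizeEpochs = as.data.frame(sizeEpochs),
      merges = as.data.frame(merges), migration = as.data.frame(migration),
      splitFractions = splitFractions, mu = mu,
      generationTime = generationTime)
}

#' Fitted three-population demographic presets
#'
#' The maximum-likelihood three-population histories fitted to the
#' Foskett Spring / Coleman Creek / Deep Creek dace system under the fast
#' (mu = 6.6e-8) and slow (mu = 1.2e-8) mutation-rate scenarios, with
#' divergence times converted from years to generations at a 2-year
#' generation time. Backward in time: Foskett and Coleman merge into the
#' Coleman-subbasin ancestor `P12` at `T2` (fast: 294 generations; slow:
#' 448) while Deep continues as the main-valley lineage `P11`; `P11` and
#' `P12` merge into the basin ancestor at `T1` (fast: 1892 generations;
#' slow: 5265). The Foskett population grows exponentially from its
#' founding size to the present; in the fast model `P11` grows linearly
#' between its endpoint sizes. Forward migration rates and split
#' fractions are the fitted values (several are exactly 0).
#'
#' @param name `"fast"` or `"slow"`.
#' @return A [DemographicModel-class].
#' @examples
#' demographicPreset("fast")
#' @export
demographicPreset <- function(name = c("fast", "slow")) {
  name <- match.arg(name)
  yr2gen <- function(y) floor(y / 2 + 0.5)  # generation time 2 yr
  if (name == "fast") {
    T2 <- yr2gen(587.5)   # 294
    T1 <- yr2gen(3783.8)  # 1892
    sizes <- data.frame(
      pop  = c("Foskett", "Coleman", "Deep", "P12", "P11", "ANC"),
      t0   = c(0, 0, 0, T2, T2, T1),
      t1   = c(T2, T2, T2, T1, T1, Inf),
      n0   = c(1076, 955, 1136, 1291, 5863, 1890),
      n1   = c(114, 955, 1136, 1291, 879, 1890),
      type = c("exponential", "constant", "constant", "constant",
               "linear", "constant"))
    mig <- data.frame(
      t0   = c(0, 0, 0, 0, 0, T2),
      t1   = c(T2, T2, T2, T2, T2, T1),
      from = c("Deep", "Coleman", "Deep", "Coleman", "Foskett", "P11"),
      to   = c("Coleman", "Deep", "Foskett", "Foskett", "Coleman", "P12"),
      rate = c(8.0e-3, 4.0e-3, 3.1e-3, 2.7e-2, 1.6e-2, 1.1e-2))
    sf <- c(Sp11 = 0.465, SpCC = 0.887)
    mu <- 6.6e-8
  } else {
    T2 <- yr2gen(896)     # 448
    T1 <- yr2gen(10529)   # 5265
    sizes <- data.frame(
      pop  = c("Foskett", "Coleman", "Deep", "P12", "P11", "ANC"),
      t0   = c(0, 0, 0, T2, T2, T1),
      t1   = c(T2, T2, T2, T1, T1, Inf),
      n0   = c(1958, 1739, 2086, 1011, 7272, 3806),
      n1   = c(198, 1739, 2086, 1011, 7272, 3806),
      type = c("exponential", "constant", "constant", "constant",
               "constant", "constant"))
    mig <- data.frame(
      t0   = c(0, 0, 0, T2),
      t1   = c(T2, T2, T2, T1),
      from = c("Deep", "Coleman", "Coleman", "P11"),
      to   = c("Coleman", "Deep", "Foskett", "P12"),
      rate = c(1.0e-3, 2.2e-4, 2.0e-3, 2.0e-3))
    sf <- c(Sp11 = 0.555, SpCC = 0.847)
    mu <- 1.2e-8
  }
  merges <- data.frame(
    time = c(T2, T2, T1, T1),
    from = c("Foskett", "Coleman", "P12", "P11"),
    to   = c("P12", "P12", "ANC", "ANC"))
  demographicModel(
    populations = c("Foskett", "Coleman", "Deep", "P12", "P11", "ANC"),
    sizeEpochs = sizes, merges = .mergeRelabel(merges, "Deep", "P11"),
    migration = mig, splitFractions = sf, mu = mu, generationTime = 2,
    name = name)
}

# backward in time Deep simply continues as P11; represent that as a merge
.mergeRelabel <- function(merges, from, to) {
  t2 <- min(merges$time)
  rbind(merges, data.frame(time = t2, from = from, to = to))
}

.typeCode <- c(constant = 0, linear = 1, exponential = 2)

#' Simulate a genotype panel under a demographic model
#'
#' Discrete-generation structured-coalescent simulation of independent
#' biallelic sites (see the package vignette for the algorithm). Two
#' haploid lineages are sampled per requested diploid; after the genealogy
#' of each site is realized, mutations are placed either as exactly one
#' mutation on a branch drawn proportionally to branch length
#' (`mutationModel = "fixed1"`, the default: every site is a segregating
#' SNP, emulating a SNP panel) or as per-branch Poisson counts at rate
#' `mu` per generation with allele state given by path parity
#' (`"poisson"`: sites may come out monomorphic and are then dropped and
#' counted, unless `dropMonomorphic = FALSE`). Diploid genotypes pair
#' consecutive sampled lineages. Optional GBS-style noise draws a
#' per-locus mean depth and masks genotypes to missing at a per-call
#' dropout rate.
#'
#' @param model a [DemographicModel-class].
#' @param samplesPerPop named integer vector: diploids sampled per
#'   population.
#' @param nSites number of independent sites.
#' @param seed RNG seed (all randomness is drawn from R's RNG).
#' @param mutationModel `"fixed1"` or `"poisson"`.
#' @param gbsNoise `NULL` for clean genotypes, or a list with elements
#'   `depthMean` (mean of the per-locus mean-depth distribution, default
#'   134), `depthShape` (gamma shape, default 4) and `dropout` (per-call
#'   missing probability, default 0.1); `TRUE` selects these defaults.
#' @param dropMonomorphic drop monomorphic sites (Poisson model only).
#' @param maxGen guard against non-coalescing models.
#' @return A list of class `"SimulatedDataset"` with `genotypes` (a
#'   [GenotypeMatrix]) and `truth` (model name, seed, per-site TMRCA and
#'   tree length, mutation counts, monomorphic-drop count; the ancestral
#'   allele is always the reference, so dosages count derived alleles).
#' @export
simulateGenotypes <- function(model, samplesPerPop, nSites, seed = NULL,
                              mutationModel = c("fixed1", "poisson"),
                              gbsNoise = NULL, dropMonomorphic = TRUE,
                              maxGen = 1e7) {
  stopifnot(is(model, "DemographicModel"))
  mutationModel <- match.arg(mutationModel)
  validObject(model)
  if (!is.null(seed)) set.seed(seed)
  pops <- model@populations
  if (is.null(names(samplesPerPop)) ||
      !all(names(samplesPerPop) %in% pops))
    stop("samplesPerPop must be named with model populations")
  nHap <- setNames(integer(length(pops)), pops)
  nHap[names(samplesPerPop)] <- 2L * as.integer(samplesPerPop)
  popIdx <- setNames(seq_along(pops) - 1L, pops)

  se <- model@sizeEpochs
  eps <- cbind(popIdx[se$pop], se$t0, pmin(se$t1, maxGen + 1), se$n0,
               se$n1, .typeCode[se$type])
  mg <- model@merges
  mg <- mg[order(mg$time), , drop = FALSE]
  mgm <- if (nrow(mg)) cbind(mg$time, popIdx[mg$from], popIdx[mg$to])
         else matrix(numeric(), 0, 3)
  mi <- model@migration
  # forward rate m[from -> to]: backward, a lineage in 'to' moves to 'from'
  mim <- if (nrow(mi)) cbind(mi$t0, mi$t1, popIdx[mi$to], popIdx[mi$from],
                             mi$rate)
         else matrix(numeric(), 0, 5)

  res <- .simSitesCpp(as.integer(nSites), unname(nHap), eps, mgm, mim,
                      if (mutationModel == "fixed1") 1L else 2L,
                      model@mu, maxGen)
  haps <- res$haplotypes
  sampled <- names(samplesPerPop)
  cols <- lapply(sampled, function(p) {
    off <- sum(nHap[seq_len(popIdx[p])])  # haploids of earlier pops
    off + seq_len(nHap[p])
  })
  names(cols) <- sampled
  genoCols <- list(); popLabel <- character(); ids <- character()
  for (p in sampled) {
    hc <- cols[[p]]
    nd <- length(hc) / 2L
    if (nd == 0) next
    gsub <- haps[, hc[2 * seq_len(nd) - 1L], drop = FALSE] +
      haps[, hc[2 * seq_len(nd)], drop = FALSE]
    genoCols[[p]] <- gsub
    popLabel <- c(popLabel, rep(p, nd))
    ids <- c(ids, sprintf("%s_%02d", p, seq_len(nd)))
  }
  gt <- do.call(cbind, genoCols)
  colnames(gt) <- ids
  rownames(gt) <- sprintf("site%05d", seq_len(nrow(gt)))
  storage.mode(gt) <- "integer"

  dropped <- 0L
  keep <- rep(TRUE, nrow(gt))
  if (mutationModel == "poisson" && dropMonomorphic) {
    mono <- apply(gt, 1, function(x) length(unique(x[!is.na(x)])) <= 1L)
    dropped <- sum(mono)
    keep <- !mono
  }
  g <- GenotypeMatrix(gt[keep, , drop = FALSE], population = popLabel)
  if (!is.null(gbsNoise) && !identical(gbsNoise, FALSE))
    g <- addGBSNoise(g, gbsNoise)
  out <- list(genotypes = g,
              truth = list(model = model@name, seed = seed,
                           mutation_model = mutationModel,
                           tmrca = res$tmrca[keep],
                           tree_length = res$tree_length[keep],
                           n_mutations = res$n_mutations[keep],
                           monomorphic_dropped = dropped))
  class(out) <- "SimulatedDataset"
  out
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset under model '%s' (seed %s)\n",
              x$truth$model,
              if (is.null(x$truth$seed)) "unset" else x$truth$seed))
  show(x$genotypes)
  invisible(x)
}

#' Overlay GBS-style depth and missingness on a genotype panel
#'
#' Draws a per-locus mean depth from a gamma distribution and masks each
#' genotype call to missing independently with the dropout probability,
#' emulating the sparse locus-by-sample structure of
#' genotyping-by-sequencing panels.
#'
#' @param g a [GenotypeMatrix].
#' @param noise list with `depthMean`, `depthShape`, `dropout` (missing
#'   entries take the defaults 134, 4, 0.1); `TRUE` selects all defaults.
#' @return The noised [GenotypeMatrix] with `mean_depth` metadata.
#' @export
addGBSNoise <- function(g, noise = TRUE) {
  defaults <- list(depthMean = 134, depthShape = 4, dropout = 0.1)
  if (isTRUE(noise)) noise <- defaults
  noise <- utils::modifyList(defaults, as.list(noise))
  gt <- genotypes(g)
  depth <- rgamma(nrow(gt), shape = noise$depthShape,
                  rate = noise$depthShape / noise$depthMean)
  mask <- matrix(runif(length(gt)) < noise$dropout, nrow(gt))
  gt[mask] <- NA_integer_
  GenotypeMatrix(gt, population = populations(g),
                 locusGroup = locusGroups(g), meanDepth = depth)
}

#' Forward Wright-Fisher simulation of unlinked loci
#'
#' Simulates a single random-mating diploid population of constant size
#' `nDiploid` at `nLoci` freely recombining biallelic loci for
#' `nGenerations` generations (initial allele frequencies uniform on
#' `initFreqRange`), then samples `sampleSize` individuals without
#' replacement. Within-generation associations among unlinked loci in the
#' finite parent pool are exactly the drift signal exploited by
#' [estimateNeLD()].
#'
#' @param nDiploid census/effective population size.
#' @param nLoci number of unlinked loci.
#' @param sampleSize individuals sampled at the end.
#' @param nGenerations generations to run (unlinked-locus LD equilibrates
#'   within a few generations; 30 is comfortable).
#' @param initFreqRange range of initial allele frequencies.
#' @param seed RNG seed.
#' @return A [GenotypeMatrix] with a single population `"pop1"`.
#' @export
simulateWrightFisher <- function(nDiploid, nLoci, sampleSize = nDiploid,
                                 nGenerations = 30L,
                                 initFreqRange = c(0.1, 0.9),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sampleSize <= nDiploid)
  p0 <- runif(nLoci, initFreqRange[1], initFreqRange[2])
  draw <- function() matrix(rbinom(nDiploid * nLoci, 1L,
                                   rep(p0, each = nDiploid)),
                            nDiploid, nLoci)
  h1 <- draw(); h2 <- draw()
  for (gen in seq_len(nGenerations)) {
    mothers <- sample.int(nDiploid, nDiploid, replace = TRUE)
    fathers <- sample.int(nDiploid, nDiploid, replace = TRUE)
    pm <- (h1[mothers, , drop = FALSE] + h2[mothers, , drop = FALSE]) / 2
    pf <- (h1[fathers, , drop = FALSE] + h2[fathers, , drop = FALSE]) / 2
    h1 <- matrix(rbinom(length(pm), 1L, pm), nDiploid, nLoci)
    h2 <- matrix(rbinom(length(pf), 1L, pf), nDiploid, nLoci)
  }
  idx <- sample.int(nDiploid, sampleSize)
  gt <- t(h1[idx, , drop = FALSE] + h2[idx, , drop = FALSE])
  storage.mode(gt) <- "integer"
  rownames(gt) <- sprintf("wf%04d", seq_len(nLoci))
  colnames(gt) <- sprintf("ind%03d", seq_len(sampleSize))
  GenotypeMatrix(gt, population = rep("pop1", sampleSize))
}
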