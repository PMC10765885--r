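#' JointSFS: joint site-frequency spectrum
#'
#' Joint SFS over 2-3 populations at chosen haploid projection sizes.
#' `counts` is an array with one dimension per population (length
#' `projection + 1`, cell `[k1+1, k2+1, ...]` holding the mass at allele
#' counts `(k1, k2, ...)`); `mask` flags cells excluded from totals: the
#' monomorphic corners and, for folded spectra, the non-canonical half
#' (mass is folded onto the lexicographically smaller of a configuration
#' and its complement).
#'
#' @slot populations population labels.
#' @slot projection haploid projection size per population.
#' @slot folded logical flag.
#' @slot counts array of (fractional) site counts.
#' @slot mask logical array, `TRUE` for excluded cells.
#' @slot dropped number of SNPs dropped for insufficient called alleles.
#' @slot nInput number of SNPs offered.
#' @export
setClass("JointSFS", representation(
  populations = "character", projection = "integer", folded = "logical",
  counts = "array", mask = "array", dropped = "integer",
  nInput = "integer"))

setValidity("JointSFS", function(object) {
  msg <- character()
  if (any(object@counts < -1e-9)) msg <- c(msg, "counts must be >= 0")
  if (!identical(dim(object@counts), object@projection + 1L))
    msg <- c(msg, "counts dimensions must equal projection + 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "JointSFS", function(object) {
  cat(sprintf("%s joint SFS over (%s), projection (%s)\n",
              if (object@folded) "Folded" else "Unfolded",
              paste(object@populations, collapse = ", "),
              paste(object@projection, collapse = ", ")),
      sprintf("  total mass %.2f from %d SNPs (%d dropped)\n",
              sfsTotal(object), object@nInput, object@dropped), sep = "")
})

#' Total unmasked SFS mass
#' @param sfs a [JointSFS-class].
#' @return numeric total.
#' @export
sfsTotal <- function(sfs) sum(sfs@counts[!sfs@mask])

#' Joint site-frequency spectrum with hypergeometric projection
#'
#' Projects each SNP down to fixed haploid sample sizes: a site with `j`
#' alternate alleles among `n` called alleles in a population contributes
#' to projected count `k` the hypergeometric probability of drawing `k`
#' alternate alleles in `m` draws without replacement, and the joint cell
#' mass is the product across populations (the deterministic expected
#' projection). Sites with fewer called alleles than the projection in any
#' population are dropped and counted. Folding (the default, for panels
#' with no outgroup polarization) is applied after projection.
#'
#' @param g a [GenotypeMatrix].
#' @param pops 2 or 3 population labels.
#' @param projection haploid projection size per population (each at most
#'   2x the population's sample count).
#' @param folded fold the spectrum onto minor-allele configurations.
#' @return A [JointSFS-class].
#' @export
jointSFS <- function(g, pops, projection, folded = TRUE) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (!length(pops) %in% 2:3) stop("2 or 3 populations are required")
  projection <- as.integer(projection)
  if (length(projection) != length(pops))
    stop("one projection size per population is required")
  pop <- populations(g)
  popCols <- lapply(pops, function(p) {
    idx <- which(pop == p)
    if (!length(idx)) stop("population is empty or unknown: ", p)
    idx
  })
  for (k in seq_along(pops))
    if (projection[k] > 2L * length(popCols[[k]]))
      stop("projection exceeds 2 x sample count for ", pops[k])
  gt <- genotypes(g)
  # per population: called allele count and alt count per SNP
  nAll <- sapply(popCols, function(idx)
    2L * rowSums(!is.na(gt[, idx, drop = FALSE])))
  jAlt <- sapply(popCols, function(idx)
    rowSums(gt[, idx, drop = FALSE], na.rm = TRUE))
  nAll <- matrix(nAll, ncol = length(pops))
  jAlt <- matrix(jAlt, ncol = length(pops))
  usable <- rowSums(nAll >= rep(projection, each = nrow(nAll))) ==
    length(pops)
  counts <- array(0, dim = projection + 1L)
  for (s in which(usable)) {
    mass <- lapply(seq_along(pops), function(k)
      dhyper(0:projection[k], jAlt[s, k], nAll[s, k] - jAlt[s, k],
             projection[k]))
    cell <- Reduce(function(a, b) outer(a, b), mass)
    counts <- counts + cell
  }
  obj <- new("JointSFS", populations = as.character(pops),
             projection = projection, folded = FALSE,
             counts = counts,
             mask = .monomorphicMask(projection),
             dropped = as.integer(sum(!usable)),
             nInput = nrow(gt))
  if (folded) foldSFS(obj) else obj
}

.monomorphicMask <- function(projection) {
  mask <- array(FALSE, dim = projection + 1L)
  zero <- matrix(1L, 1, length(projection))
  full <- matrix(projection + 1L, 1, length(projection))
  mask[zero] <- TRUE
  mask[full] <- TRUE
  mask
}

#' Fold a joint SFS onto minor-allele configurations
#'
#' Adds the mass of every configuration and its complement into the
#' lexicographically smaller of the two (the canonical fold), masking the
#' non-canonical half. Folding an already folded spectrum is a no-op.
#'
#' @param sfs a [JointSFS-class].
#' @return The folded [JointSFS-class].
#' @export
foldSFS <- function(sfs) {
  if (sfs@folded) return(sfs)
  dims <- dim(sfs@counts)
  grid <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1))))
  comp <- sweep(-grid, 2, sfs@projection, `+`)
  canonical <- vapply(seq_len(nrow(grid)), function(r) {
    a <- grid[r, ]; b <- comp[r, ]
    cmp <- a - b
    nz <- which(cmp != 0)
    if (!length(nz)) TRUE else cmp[nz[1]] < 0
  }, logical(1))
  counts <- array(0, dim = dims)
  idx <- grid + 1L
  cidx <- comp + 1L
  for (r in seq_len(nrow(grid))) {
    if (canonical[r]) {
      self <- all(grid[r, ] == comp[r, ])
      counts[matrix(idx[r, ], 1)] <-
        sfs@counts[matrix(idx[r, ], 1)] +
        if (self) 0 else sfs@counts[matrix(cidx[r, ], 1)]
    }
  }
  mask <- .monomorphicMask(sfs@projection) | !array(canonical, dim = dims)
  initialize(sfs, folded = TRUE, counts = counts, mask = mask)
}

#' Bootstrap the joint SFS over SNPs
#'
#' Resamples SNP columns with replacement to the original count and
#' recomputes the joint SFS; seeded and reproducible.
#'
#' @inheritParams jointSFS
#' @param reps number of bootstrap replicates.
#' @param seed RNG seed.
#' @return A list of [JointSFS-class] replicates.
#' @export
bootstrapSFS <- function(g, pops, projection, folded = TRUE,
                         reps = 100L, seed = NULL) {
  stopifnot(reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(r) {
    idx <- sample.int(nLoci(g), nLoci(g), replace = TRUE)
    jointSFS(g[idx, ], pops, projection, folded)
  })
}

#' Serialize / read a joint SFS in dadi-style flat text
#'
#' A three-line plain-text format: a header of dimension sizes plus
#' `folded`/`unfolded`, the flattened counts (last population index
#' varying fastest, i.e. C order), and a mask line of 0/1 in the same
#' order.
#'
#' @param sfs a [JointSFS-class].
#' @param path output file.
#' @return `path` invisibly; `readSFS()` returns a [JointSFS-class] (with
#'   unknown provenance fields zeroed).
#' @export
writeSFS <- function(sfs, path) {
  dims <- dim(sfs@counts)
  corder <- function(a) as.vector(aperm(a, rev(seq_along(dims))))
  lines <- c(
    paste(c(dims, if (sfs@folded) "folded" else "unfolded",
            paste0('"', sfs@populations, '"')), collapse = " "),
    paste(format(corder(sfs@counts), digits = 12, trim = TRUE),
          collapse = " "),
    paste(as.integer(corder(sfs@mask)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSFS
#' @export
readSFS <- function(path) {
  lines <- readLines(path)
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ndim <- sum(!is.na(suppressWarnings(as.integer(head))) &
                !grepl('"', head))
  dims <- as.integer(head[seq_len(ndim)])
  folded <- identical(head[ndim + 1L], "folded")
  pops <- gsub('"', "", head[-(seq_len(ndim + 1L))])
  if (!length(pops)) pops <- paste0("pop", seq_len(ndim))
  decode <- function(x, mode) {
    v <- as(strsplit(trimws(x), "\\s+")[[1]], mode)
    aperm(array(v, dim = rev(dims)), rev(seq_along(dims)))
  }
  counts <- decode(lines[2], "numeric")
  mask <- decode(lines[3], "integer") == 1L
  new("JointSFS", populations = pops, projection = dims - 1L,
      folded = folded, counts = counts, mask = mask,
      dropped = 0L, nInput = 0L)
}

#' Multinomial goodness of fit between two spectra
#'
#' Log-likelihood of the observed unmasked cell masses under the cell
#' probabilities implied by an expected spectrum (e.g. one simulated under
#' a fitted demographic model). No optimization is performed.
#'
#' @param observed,expected [JointSFS-class] objects on the same
#'   projection.
#' @return The multinomial log-likelihood (a negative number).
#' @export
sfsLogLik <- function(observed, expected) {
  stopifnot(identical(dim(observed@counts), dim(expected@counts)))
  use <- !observed@mask & !expected@mask
  p <- expected@counts[use]
  p <- p / sum(p)
  o <- observed@counts[use]
  keep <- o > 0
  if (any(p[keep] == 0)) return(-Inf)
  sum(o[keep] * log(p[keep]))
}

#' Convert calendar years to generations
#'
#' @param tYears time in years (nonnegative).
#' @param generationTime generation time in years (default 2, the typical
#'   age at first reproduction for small stream-dwelling dace).
#' @return `tYears / generationTime`.
#' @examples
#' yearsToGenerations(588)  # 294
#' yearsToGenerations(896)  # 448
#' @export
yearsToGenerations <- function(tYears, generationTime = 2) {
  stopifnot(all(tYears >= 0), generationTime > 0)
  tYears / generationTime
}

#' Expected generations for drift to fixation
#'
#' The classical neutral expectation that a new polymorphism takes on the
#' order of `4 Ne` generations to drift to fixation in a diploid
#' population of effective size `Ne`.
#'
#' @param ne diploid effective population size (> 0).
#' @return `4 * ne` generations.
#' @examples
#' driftFixationGenerations(1076)  # 4304
#' @export
driftFixationGenerations <- function(ne) {
  stopifnot(all(ne > 0))
  4 * ne
}
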