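---
title: "Models and methods behind dacepop"
author: "dacepop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dacepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dacepop analyses diploid biallelic SNP panels from small, structured fish
populations — the kind produced by genotyping-by-sequencing of a few dozen
individuals per site — and ships a coalescent simulator so that the whole
chain is testable with no sequencing data. This vignette records the
models, the parameter choices and their rationale, the numerical
decisions, and what the simulation-based tests do and do not establish.

## The data model

`GenotypeMatrix` extends `SummarizedExperiment`: one integer assay of
alternate-allele dosages (0/1/2, `NA` missing) with loci as rows and
samples as columns; `colData$population` is mandatory, and `rowData`
carries the assembly-locus tag used by the one-SNP-per-locus filter plus
optional coordinates and per-locus mean depth. Dosage coding makes every
statistic a function of allele counts; all estimators are invariant to
swapping the allele labels at any locus (0 <-> 2), and the tests assert
this property directly.

## Quality control

Locus filters run in a fixed order (call rate, minor allele count, excess
depth, first SNP per locus), each reported separately:

- **Per-population call rate**, default ≥ 0.80 in every population
  (non-strict at the boundary). Requiring every population guards against
  loci genotyped in only part of the landscape.
- **Minor allele count**, pooled over all samples, default ≥ 3. Pooling
  matches the single panel-wide flag the assembler applies; a
  per-population MAC is not offered because the assembler semantics are
  global.
- **Excess depth**: loci above `mean + 2 SD` of the per-locus mean depths
  are removed as probable merged paralogs. The rule only engages when
  depth metadata exist; note that a single extreme locus inflates the SD,
  so the screen is effective only when the depth panel is reasonably
  large.
- **First SNP per assembly locus**, in input order, so retained SNPs are
  exchangeable with an "independent loci" assumption downstream.

Samples with genotyping rate strictly below 0.70 are removed ("< 70%"
semantics: exactly 70% is kept).

**Relatives.** KING-robust kinship is computed pairwise over shared called
loci: `phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`. The estimator is
robust to population structure because it conditions on the pair's own
heterozygous sites. Degrees use the standard powers-of-½ midpoints:
duplicate > 0.354, 1st degree (0.177, 0.354], 2nd degree (0.0884, 0.177].
Pruning flags pairs with `phi > 0.0884` (strictly above, so that flagging
coincides exactly with "2nd degree or closer") and greedily removes the
sample in the most flagged pairs, ties broken lexicographically — one
member per isolated pair, only the hub of a star. Pairs sharing no
heterozygous locus have an undefined phi and are flagged `undefined`, not
pruned.

Diversity statistics can be computed on the matrix before or after
relative pruning — the pipeline prunes first, but each stage is a plain
function, so either order is available when a study reports
pre-pruning diversity.

## Diversity and differentiation

Per locus and population with `n ≥ 2` called diploids and alternate
frequency `p`: `H_O = n_het / n` and Nei's unbiased
`H_E = 2 p (1 - p) · 2n/(2n - 1)`. Population means average over all
qualifying loci, monomorphic loci contributing zeros — dropping them would
inflate both quantities. `F_IS = 1 - H̄_O / H̄_E` is the ratio of means,
not the mean of per-locus ratios, because per-locus `F_IS` is unstable
when `H_E` is tiny; per-locus tables are returned for diagnostics, and
the estimator choice is recorded in the output.

Pairwise F_ST is the Weir–Cockerham 1984 two-level moment estimator:
per-locus variance components `a` (among populations), `b` (among
individuals within), `c` (within individuals), combined across loci as
the weighted ratio of sums `theta = Σa / Σ(a+b+c)`. Loci monomorphic
across a pair are excluded (their components are identically zero).
Slightly negative estimates are legitimate for undifferentiated pairs and
are never clipped in the reported matrix; they are floored at zero only
when the matrix is used as a distance for neighbor joining. NJ
agglomeration is `ape::nj`; negative branch lengths are clamped to zero
with the deficit transferred to the sibling branch, preserving
adjacent-pair path lengths.

**What theta estimates.** Under a clean split of duration `T` with
constant diploid size `N`, the ratio-of-sums estimator converges to the
coalescent-time ratio `1 - T̄_w/T̄_b = T / (T + 2N)` (within-pair mean
coalescence time `2N`, cross-pair `T + 2N`). The familiar
`1 - exp(-T/(2N))` is the allele-frequency-variance form relative to the
*ancestral* heterozygosity and agrees with the time ratio only when
`T ≪ 2N`. The test suite asserts the time-ratio form at `T/2N = 0.25`,
where the two differ measurably, and exercises the exponential form at
`T/2N = 0.05`, inside its validity domain.

PCA imputes each missing dosage with the sample's population mean at the
locus (global mean if the population is entirely missing), then centers
and unit-scales columns, dropping zero-variance columns rather than
erroring. Component signs are fixed so the first sample scores
nonnegative, making runs comparable.

## LD effective population size

For a focal population, loci are screened at within-population MAF ≥ 0.01
(the default used for the shipped analyses; 0.02–0.05 is a common
stricter choice and reduces the small upward bias low-MAF loci induce).
For every locus pair, `r̂²` is the squared Pearson correlation of dosages
over samples called at both loci; the mean is weighted by pairwise sample
size, and the harmonic-mean `S` enters the expectation.

Two calibration decisions were made on simulated Wright–Fisher data and
are worth recording:

- **Sampling expectation.** For the plain Pearson `r̂²` the null
  expectation at sample size `S` is `1/(S-1)` (exact for independent
  loci). The published `1/(S-1) + 3.19/(S-1)²` refinement is an empirical
  calibration for the Burrows-composite `r̂²` as computed by the original
  LD-Ne software; applied to the Pearson form it over-subtracts, which at
  `S ≪ N` wipes out the drift signal entirely (all estimates Infinite)
  and at `S = N = 50` biases the median estimate to ~75. With `1/(S-1)`,
  median recovery on true sizes 25/50/100/200 is 27/55/114/240 at MAF
  0.01 and essentially unbiased at MAF 0.05.
- **Confidence interval.** The drift signal is shared pedigree noise, so
  a delete-one-locus jackknife (which only sees locus-sampling noise) is
  anticonservative: measured coverage 57–75%. The default CI is therefore
  a delete-one-sample jackknife (coverage 90–98% across the same
  designs); the locus jackknife remains available via
  `ciMethod = "loci"`. The method used is recorded in the output.

The drift inversion is the random-mating quadratic
`N̂e = (1/3 + sqrt(1/9 - 2.76 r²'))/(2 r²')` for `S ≥ 30` (small-sample
constants 0.308/2.08 below that), with `r²' ≤ 0` mapping to `Infinite` —
the correct report when drift is undetectable at the sample size, as for
large stream populations. CI bounds pass through the same inversion, so
an upper bound of `Infinite` is common and meaningful.

## Three-sample D3

Individual genetic distances are allele-sharing IBS:
`d(i,j) = mean(|g_i - g_j|)/2` over shared called loci, so identical
genotypes give 0, het-vs-hom 0.5, opposite homozygotes 1. For a trio with
sister pair (A, B) and third population C,
`D3 = (d_BC - d_AC)/(d_BC + d_AC)` is evaluated for every individual
triple. The sign convention follows directly from the formula: gene flow
between A and C shortens `d_AC` and drives D3 positive; B–C flow drives
it negative; the convention string is carried in every result object.
Swapping A and B negates every value, and D3 is invariant to rescaling
all distances — both are property-tested.

Three intervals are reported. The Z interval
(`mean ± 1.96 sd/√n_triples`) mirrors common practice but treats triples
as independent when they share individuals and loci; under a simulated
no-gene-flow null its coverage of zero is essentially 0%. The
block-jackknife over loci (20 contiguous blocks by default) targets the
real replication unit and covers the null in ≥ 90% of simulated
replicates; it is the interval the package's own calibration tests use.
Empirical 2.5/97.5% quantiles of the triple distribution are also given.
Triple enumeration above `maxTriples` (default 10⁶) falls back to a
seeded subsample.

## Joint SFS

Each SNP with `j` alternate alleles among `n` called alleles in a
population contributes `P(K = k) = choose(j,k) choose(n-j, m-k) /
choose(n,m)` to projected count `k` at haploid projection `m` — the
deterministic hypergeometric (expected) projection; sites with `n < m` in
any population are dropped and counted, so total mass plus drops equals
the input SNP count. Folding (the default, appropriate without outgroup
polarization) adds each configuration to its complement in the
lexicographically smaller cell and masks the non-canonical half along
with the monomorphic corners. The SNP bootstrap resamples loci with
replacement, seeded. Spectra serialize to a dadi-style three-line flat
text (dimensions + fold flag, C-order counts, mask). Model comparison is
by plain multinomial log-likelihood (`sfsLogLik`); no diffusion
optimization is included, by design — the simulator provides expected
spectra instead.

Analytic conversions used alongside: generations = years / generation
time (2 years for these dace, the typical age at first reproduction), and
the `4 Ne` rule of thumb for generations to drift fixation.

## The coalescent simulator

Backward time runs in whole generations. Each generation: (1) merges
whose time is reached move lineages from daughter to parent deme; (2)
each lineage in deme `b` jumps to deme `a` with the backward probability
equal to the forward fraction `m[a→b]` of `b` replaced by migrants from
`a`; (3) within each deme every lineage picks a parent chromosome
uniformly among `2N(t)`, and lineages sharing a parent coalesce —
multiple mergers included, i.e. the exact discrete Wright–Fisher
ancestral process rather than its continuous approximation. When exactly
two lineages remain co-located with constant size and no migration band
or merge before the next boundary, the geometric waiting time to
coalescence is drawn in one step; this is an exact shortcut, not an
approximation, and the per-generation and shortcut paths agree on
calibration (pairwise time `2N` and the 4-haploid `3N` expectation both
within Monte-Carlo error).

Size trajectories are per-epoch constant, linear, or exponential
(`N(t) = n0 (n1/n0)^{(t-t0)/(t1-t0)}`), interpolating the endpoint sizes
a fitted model reports; where a fitted history names only endpoints, the
full epoch span is used. Forward split fractions are carried as metadata:
backward they influence nothing but the daughter sizes, which the size
table already encodes — a deliberate difference from diffusion
parameterizations, noted here because the two conventions are easy to
conflate.

Mutation has two modes. `fixed1` (default) places exactly one mutation on
a branch drawn proportionally to branch length — every site is a
segregating biallelic SNP, emulating a SNP panel; conditioning ignores
the length-biased weighting across sites, the standard fixed-S
simplification. `poisson` draws per-branch Poisson(μ·len) counts and
assigns alleles by path parity (a two-allele recurrent-mutation model);
it is the mode for closed-form checks such as pairwise diversity
`≈ 4Nμ`, which the tests run at `4Nμ = 0.04` where parity saturation is
negligible. GBS noise overlays a gamma per-locus mean depth (defaults:
mean 134×, shape 4, matching deep GBS panels) and masks calls at a 10%
dropout rate, which lands post-filter call rates near the 80–90% regime
typical of such panels.

`demographicPreset("fast"|"slow")` encodes the fitted three-population
histories for the dace system: present-day Foskett/Coleman/Deep demes,
the Coleman-subbasin ancestor `P12` and main-valley lineage `P11` merging
at `T2` (fast 294, slow 448 generations; 2-year generations), the basin
ancestor at `T1` (fast 1892, slow 5265), exponential Foskett growth from
its founding size (fast 114 → 1076; slow 198 → 1958), fast-model linear
`P11` growth (879 → 5863), and the fitted asymmetric migration matrix
(several rates exactly zero, e.g. Foskett → Deep). Under the fast preset
the end-to-end chain reproduces the system's qualitative signature —
F_ST(Foskett, Coleman) < F_ST(Foskett, Deep) and positive trio D3 for
sisters (Foskett, Deep) — and those orderings, not the printed
magnitudes, are what the acceptance tests assert: simulated absolute
F_ST under the fitted histories (~0.005–0.02) sits well below the
observed panel values, as expected when high fitted migration rates and
modest sizes are simulated without the ascertainment and linked-locus
structure of a real panel.

A forward companion, `simulateWrightFisher`, simulates a single
random-mating diploid population at freely recombining loci and is the
calibration substrate for the LD-Ne estimator (unlinked-locus LD
equilibrates within a few generations; 30 are run).

## Problem sizes in the shipped tests

The default test run uses deliberately small designs chosen to keep the
suite brisk while leaving comfortable statistical margins: D3 null and
directional calibrations at 100/50 replicates of 15 diploids × 1,000
sites; the end-to-end preset check at 20 replicates of 3,354 sites with
45/44/20 samples; LD-Ne recovery at 50 Wright–Fisher replicates of 500
loci; closed-form checks at 6–8 replicates of 8,000–12,000 sites. The
acceptance script re-runs the headline D3 null at its full design (100 ×
30 diploids × 2,000 sites).

## Limitations

Sites are simulated independently: no within-locus recombination, no
linked selection, no ascertainment of the SNP discovery process, and the
parity mutation model is not a sequence-level mutation model. The Z
interval for D3 is reported for comparability but should not be used for
inference — use the locus jackknife. LD-Ne assumes a closed, randomly
mating population and unlinked loci; violations (admixture, overlapping
generations, physical linkage) bias it in known directions. Passing the
simulation-based tests shows the estimators are correctly implemented and
calibrated under these idealized conditions, not that any particular
empirical dataset meets them.
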