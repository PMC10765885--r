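#' Run the full analysis pipeline
#'
#' Orchestrates the analysis chain on either a simulated or a user-supplied
#' panel: input -> locus QC -> sample QC -> relative pruning -> diversity ->
#' pairwise F_ST / NJ dendrogram / PCA -> LD-Ne per population -> D3 trios
#' -> joint SFS (with optional bootstrap). All artifacts are written under
#' `outdir` and a machine-readable run report is returned (and written as
#' `report.json`). Given the same configuration and seed the run is
#' deterministic.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 42
#' outdir: run1
#' input:                      # either a preset block ...
#'   preset: fast
#'   samples: {Foskett: 45, Coleman: 44, Deep: 20}
#'   sites: 3354
#'   gbs_noise: true
#' # ... or files:
#' #  vcf: panel.vcf          # (or tsv: panel.tsv)
#' #  popmap: samples.tsv
#' qc: {min_call_rate: 0.80, min_mac: 3, depth_sd: 2.0,
#'      min_sample_call_rate: 0.70, kinship_cutoff: 0.0884,
#'      first_snp_only: true}
#' ne: {maf_cutoff: 0.01}
#' d3:
#'   trios:
#'     - {A: Foskett, B: Deep, C: Coleman}
#' sfs: {pops: [Foskett, Coleman, Deep], projection: [20, 20, 20],
#'       folded: true, bootstrap: 0}
#' }
#'
#' @param config path to a YAML configuration file, or a list.
#' @return The run report (list), invisibly also written to
#'   `outdir/report.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validatePipelineConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  report <- list(config = cfg, version = as.character(packageVersion("dacepop")),
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # input
  g <- stage("input", {
    if (!is.null(cfg$input$preset)) {
      model <- demographicPreset(cfg$input$preset)
      sim <- simulateGenotypes(
        model, unlist(cfg$input$samples), cfg$input$sites, seed = seed,
        gbsNoise = if (isTRUE(cfg$input$gbs_noise)) TRUE else NULL)
      sim$genotypes
    } else if (!is.null(cfg$input$vcf)) {
      readGenotypes(cfg$input$vcf, cfg$input$popmap, format = "vcf")
    } else {
      readGenotypes(cfg$input$tsv, cfg$input$popmap, format = "tsv")
    }
  })
  report$stages$input <- list(n_samples = ncol(g), n_loci = nrow(g))

  # locus + sample QC, then relative pruning
  qc <- .qcFromConfig(cfg$qc)
  fl <- stage("filter_loci", filterLoci(g, qc))
  fs <- stage("filter_samples", filterSamples(fl$genotypes, qc))
  kin <- stage("kinship", kingKinship(fs$genotypes))
  pr <- stage("prune_relatives", pruneRelatives(fs$genotypes, kin, qc))
  g2 <- pr$genotypes
  report$stages$qc <- list(
    locus_filter = fl$report, sample_filter = fs$report,
    relatives_removed = pr$removed,
    n_samples = ncol(g2), n_loci = nrow(g2))
  writeGenotypes(g2, file.path(cfg$outdir, "filtered.tsv"))
  writePopmap(g2, file.path(cfg$outdir, "filtered_popmap.tsv"))

  # diversity, F_ST, NJ, PCA
  div <- stage("diversity", diversitySummary(g2))
  write.csv(div$summary, file.path(cfg$outdir, "diversity.csv"),
            row.names = FALSE)
  report$stages$diversity <- div$summary
  pops <- unique(populations(g2))
  if (length(pops) >= 2) {
    fst <- stage("fst", pairwiseFst(g2))
    write.csv(fst$fst, file.path(cfg$outdir, "fst.csv"))
    report$stages$fst <- fst$fst
    if (length(pops) >= 3) {
      nwk <- stage("nj", njDendrogram(fst$fst))
      writeLines(nwk, file.path(cfg$outdir, "nj.nwk"))
      report$stages$nj <- nwk
    }
  }
  pca <- stage("pca", pcaAlleleFreq(g2))
  write.csv(data.frame(sample = rownames(pca$scores),
                       population = populations(g2), pca$scores),
            file.path(cfg$outdir, "pca_scores.csv"), row.names = FALSE)
  report$stages$pca <- list(explained = pca$explained,
                            n_loci_used = pca$n_loci_used)

  # LD-Ne per population
  report$stages$ne <- lapply(setNames(nm = pops), function(p) {
    est <- tryCatch(
      estimateNeLD(g2, p, mafCutoff = cfg$ne$maf_cutoff %||% 0.01),
      error = function(e) NULL)
    if (is.null(est)) return(list(error = "estimation failed"))
    list(ne = est@ne, ci = c(est@ciLower, est@ciUpper),
         r2_mean = est@r2Mean, r2_expected = est@r2Expected,
         n_comparisons = est@nComparisons, n_loci = est@nLoci)
  })

  # D3 trios
  if (length(cfg$d3$trios)) {
    report$stages$d3 <- lapply(cfg$d3$trios, function(tr) {
      res <- stage("d3", d3Trio(g2, tr$A, tr$B, tr$C, seed = seed))
      write.csv(data.frame(d3 = res@values),
                file.path(cfg$outdir,
                          sprintf("d3_%s_%s_%s.csv", tr$A, tr$B, tr$C)),
                row.names = FALSE)
      list(A = res@popA, B = res@popB, C = res@popC, mean = res@mean,
           ci = c(res@ciLower, res@ciUpper), n_triples = res@nTriples,
           interpretation = res@interpretation)
    })
  }

  # joint SFS
  if (!is.null(cfg$sfs)) {
    sfs <- stage("sfs", jointSFS(g2, unlist(cfg$sfs$pops),
                                 unlist(cfg$sfs$projection),
                                 folded = cfg$sfs$folded %||% TRUE))
    writeSFS(sfs, file.path(cfg$outdir, "joint_sfs.txt"))
    report$stages$sfs <- list(total = sfsTotal(sfs),
                              dropped = sfs@dropped,
                              file = "joint_sfs.txt")
    reps <- cfg$sfs$bootstrap %||% 0L
    if (reps > 0) {
      boots <- stage("sfs_bootstrap",
                     bootstrapSFS(g2, unlist(cfg$sfs$pops),
                                  unlist(cfg$sfs$projection),
                                  folded = cfg$sfs$folded %||% TRUE,
                                  reps = reps, seed = seed))
      bdir <- file.path(cfg$outdir, "sfs_bootstrap")
      dir.create(bdir, showWarnings = FALSE)
      for (i in seq_along(boots))
        writeSFS(boots[[i]], file.path(bdir, sprintf("rep%03d.txt", i)))
      report$stages$sfs$bootstrap_reps <- reps
    }
  }

  report$seed <- seed
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validatePipelineConfig <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or YAML file")
  if (is.null(cfg$input)) stop("config validation: 'input' block required")
  inp <- cfg$input
  if (!is.null(inp$preset)) {
    if (is.null(inp$samples) || is.null(inp$sites))
      stop("config validation: preset input needs 'samples' and 'sites'")
  } else if (!is.null(inp$vcf) || !is.null(inp$tsv)) {
    if (is.null(inp$popmap))
      stop("config validation: file input needs 'popmap'")
  } else {
    stop("config validation: 'input' needs a 'preset' or a 'vcf'/'tsv'")
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$outdir <- cfg$outdir %||% "dacepop_run"
  cfg$qc <- cfg$qc %||% list()
  cfg$ne <- cfg$ne %||% list()
  cfg$d3 <- cfg$d3 %||% list(trios = list())
  cfg
}

.qcFromConfig <- function(q) {
  qcConfig(
    minCallRate = q$min_call_rate %||% 0.80,
    minPopulations = q$min_populations %||% NA_integer_,
    minMAC = q$min_mac %||% 3L,
    depthSDThreshold = q$depth_sd %||% 2.0,
    minSampleCallRate = q$min_sample_call_rate %||% 0.70,
    kinshipCutoff = q$kinship_cutoff %||% 0.0884,
    firstSNPOnly = q$first_snp_only %||% TRUE)
}
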