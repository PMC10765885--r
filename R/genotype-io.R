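#' Read a genotype panel from VCF or TSV
#'
#' Reads biallelic SNP genotypes into a [GenotypeMatrix]. For VCF input only
#' the GT field is used; sites that are not biallelic SNPs are skipped (the
#' count is reported via `message()` and attached as metadata). Population
#' labels come from a two-column sample-map file (`sample<TAB>population`,
#' no header).
#'
#' The TSV genotype format is a plain rectangular table: a header row of
#' locus identifiers, one row per sample whose first column is the sample
#' identifier, and cells in \{0, 1, 2, NA\}.
#'
#' @param path path to the genotype file.
#' @param popmap path to the sample-map TSV, or a named character vector of
#'   population labels keyed by sample id.
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @return A [GenotypeMatrix]. The number of skipped non-biallelic sites is
#'   stored in `metadata(x)$skipped_non_biallelic`.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, popmap, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  pops <- if (is.character(popmap) && !is.null(names(popmap))) popmap
          else readPopmap(popmap)
  if (format == "vcf") .readVcfGenotypes(path, pops)
  else .readTsvGenotypes(path, pops)
}

#' Read a sample-map file
#'
#' @param path two-column TSV (`sample<TAB>population`, no header).
#' @return named character vector of population labels.
#' @export
readPopmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("sample", "population"))
  if (anyDuplicated(pm$sample))
    stop("duplicated sample ids in sample map: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  setNames(pm$population, pm$sample)
}

.checkPopmap <- function(sampleIds, pops) {
  missing <- setdiff(sampleIds, names(pops))
  if (length(missing))
    stop("samples absent from the sample map: ",
         paste(missing, collapse = ", "))
  pops[sampleIds]
}

.getFixMatrix <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-site VCF
  fix
}

.readVcfGenotypes <- function(path, pops) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  keep <- vcfR::is.biallelic(vcf)
  # restrict to SNPs: REF and single ALT both one base
  fix <- .getFixMatrix(vcf)
  snp <- nchar(fix[, "REF"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "ALT"]) == 1L & !is.na(fix[, "ALT"])
  keep <- keep & snp
  skipped <- sum(!keep)
  if (skipped > 0)
    message(skipped, " non-biallelic-SNP site(s) skipped")
  vcf <- vcf[keep, ]
  gtchar <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(NA_integer_, nrow(gtchar), ncol(gtchar),
               dimnames = dimnames(gtchar))
  alleles <- gsub("[|/]", "", gtchar)
  gt[alleles %in% c("00")] <- 0L
  gt[alleles %in% c("01", "10")] <- 1L
  gt[alleles %in% c("11")] <- 2L
  unparsed <- !is.na(gtchar) & is.na(gt) & !alleles %in% c(".", "..")
  if (any(unparsed))
    stop("unparseable GT value(s), e.g. ",
         gtchar[which(unparsed)[1]])
  fix <- .getFixMatrix(vcf)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  rownames(gt) <- make.unique(ids)
  # locus group: ID prefix before ':' if present (assembler convention),
  # otherwise each SNP is its own locus
  grp <- sub(":.*$", "", rownames(gt))
  population <- .checkPopmap(colnames(gt), pops)
  g <- GenotypeMatrix(gt, population = population, locusGroup = grp,
                      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  metadata(g)$skipped_non_biallelic <- skipped
  g
}

.readTsvGenotypes <- function(path, pops) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, row.names = 1,
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV genotype file '", path, "': ",
                             conditionMessage(e)))
  m <- as.matrix(tab)
  bad <- which(!(is.na(m) | m %in% c("0", "1", "2", 0, 1, 2)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "malformed genotype '%s' at line %d (sample %s, locus %s)",
      m[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  storage.mode(m) <- "integer"
  gt <- t(m)  # file is samples x loci; container is loci x samples
  population <- .checkPopmap(colnames(gt), pops)
  GenotypeMatrix(gt, population = population)
}

#' Write a genotype panel to TSV or minimal VCF
#'
#' The TSV writer emits the rectangular samples-by-loci table described in
#' [readGenotypes()]; `writeGenotypes()` followed by `readGenotypes()` is an
#' identity on genotypes, sample ids and locus ids. The VCF writer emits a
#' minimal VCF v4.2 with GT-only genotype columns (chrom/pos taken from
#' locus metadata when present, placeholders otherwise).
#'
#' @param g a [GenotypeMatrix].
#' @param path output file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  gt <- genotypes(g)
  if (format == "tsv") {
    tab <- t(gt)
    df <- data.frame(sample = rownames(tab), tab, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rd <- rowData(g)
    chrom <- if ("chrom" %in% colnames(rd)) rd$chrom else rownames(g)
    pos <- if ("pos" %in% colnames(rd)) rd$pos else seq_len(nrow(g))
    gtcode <- c("0/0", "0/1", "1/1")
    body <- matrix("./.", nrow(gt), ncol(gt))
    ok <- !is.na(gt)
    body[ok] <- gtcode[gt[ok] + 1L]
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", colnames(gt)), collapse = "\t"),
      paste(chrom, pos, rownames(gt), "A", "T", ".", "PASS", ".", "GT",
            apply(body, 1, paste, collapse = "\t"), sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a sample-map file for a genotype panel
#'
#' @param g a [GenotypeMatrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePopmap <- function(g, path) {
  write.table(data.frame(colnames(g), populations(g)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
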