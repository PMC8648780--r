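#' Read a VCF into a GenotypeMatrix
#'
#' Parses a VCF v4.x with GT fields via \code{vcfR}, keeping biallelic
#' SNP records only (multiallelic records are skipped with a count, or
#' rejected when \code{multiallelic = "error"}). Dosage counts the
#' minor allele as determined from the file's own samples; missing GT
#' (./.) becomes NA; 1-based positions are preserved.
#'
#' @param path VCF file (plain or bgzipped).
#' @param multiallelic "skip" or "error".
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readVcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)   # single-record files drop to vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  snp <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!snp)) {
    if (multiallelic == "error")
      stop(sum(!snp), " non-biallelic-SNP record(s), first at line with POS ",
           fix$POS[which(!snp)[1]])
    message("skipping ", sum(!snp), " non-biallelic-SNP record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  count_alt <- function(g) {
    # tolerate phased separators; NA for missing
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), numeric(1)))
  }
  d <- t(apply(gt, 1, count_alt))
  if (nrow(gt) == 1) d <- matrix(d, nrow = 1)
  dosage <- t(d)
  rownames(dosage) <- colnames(gt)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  colnames(dosage) <- ids
  GenotypeMatrix(dosage,
                 data.frame(id = ids, chrom = fix$CHROM,
                            pos = as.integer(fix$POS), ref = fix$REF,
                            alt = fix$ALT))
}

#' Write a GenotypeMatrix as VCF v4.2
#'
#' Emits a minimal GT-only VCF. Genotypes are written as unphased
#' alt-allele counts (0/0, 0/1, 1/1, ./.), reconstructed from the
#' minor-allele dosage and the minor-allele label.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeVcf <- function(genotypes, path) {
  v <- variantInfo(genotypes)
  d <- dosages(genotypes)
  alt_dos <- d
  flip <- v$minor_allele != v$alt
  if (any(flip)) alt_dos[, flip] <- 2 - alt_dos[, flip]
  gtcode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(d)),
                     collapse = "\t")),
             con)
  for (j in seq_len(ncol(d))) {
    g <- ifelse(is.na(alt_dos[, j]), "./.", gtcode[alt_dos[, j] + 1])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a taxa relative-abundance profile from TSV
#'
#' Expects a header row, sample ids in the first column, one numeric
#' column per taxon, "NA" as the missing token. Duplicate sample or
#' taxon ids and abundances outside [0, 1] are rejected.
#'
#' @param path TSV file.
#' @param taxonomy optional named lineage vector to attach.
#' @return a \linkS4class{TaxaProfile}.
#' @export
readProfile <- function(path, taxonomy = character()) {
  df <- readTable(path)
  a <- as.matrix(df)
  if (any(a < 0 | a > 1, na.rm = TRUE))
    stop("abundances outside [0, 1] in ", path)
  TaxaProfile(a, taxonomy)
}

#' Read a covariate/phenotype table from TSV
#'
#' Header row, sample ids in the first column, numeric columns, "NA"
#' missing token; ragged rows and duplicate ids are errors.
#'
#' @param path TSV file.
#' @return data.frame with sample ids as rownames.
#' @export
readTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = "NA")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample ids in ", path)
  rownames(df) <- df[[1]]
  df[[1]] <- NULL
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(x))
      if (any(is.na(xn) & !is.na(x)))
        stop("non-numeric value in column '", names(df)[j], "' of ", path)
      df[[j]] <- xn
    }
  }
  df
}

#' Write a simulated cohort to disk
#'
#' Emits, per cohort directory: genotypes.vcf, taxa_profile.tsv,
#' covariates.tsv, phenotypes.tsv; plus truth.json and manifest.json
#' (config + seed) at the top level. A re-run with the same seed is
#' byte-identical except for the manifest timestamp.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
writeCohort <- function(cohort, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  one <- function(part, sub) {
    dd <- file.path(outdir, sub)
    dir.create(dd, showWarnings = FALSE)
    writeVcf(part$genotypes, file.path(dd, "genotypes.vcf"))
    writeTsv(abundances(part$taxa), file.path(dd, "taxa_profile.tsv"))
    writeTsv(part$covariates, file.path(dd, "covariates.tsv"))
    writeTsv(part$phenotypes, file.path(dd, "phenotypes.tsv"))
  }
  one(cohort$discovery, "discovery")
  if (!is.null(cohort$replication)) one(cohort$replication, "replication")
  truth <- cohort$truth
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(config = unclass(cohort$config),
                   seed = cohort$config$seed,
                   n_snps = nrow(cohort$panel),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
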