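#' @import methods
#' @importFrom stats sd median cor qchisq pchisq pnorm pf pt qnorm rbinom
#'   rnorm runif complete.cases lm glm binomial coef p.adjust wilcox.test
#'   quantile cmdscale dist prcomp var chisq.test setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

#' GenotypeMatrix: per-sample minor-allele dosages plus variant metadata
#'
#' Samples are rows, variants are columns. Dosages count copies of the
#' stated minor allele (0/1/2, NA allowed). Variant metadata carries
#' chromosome, 1-based position, ref/alt alleles, the minor allele, and
#' per-variant QC statistics (MAF, HWE p, call rate) which are recomputed
#' from the dosage matrix by the constructor.
#'
#' @slot dosage numeric matrix, samples x variants, values in {0,1,2,NA}.
#' @slot variants data.frame with columns id, chrom, pos, ref, alt,
#'   minor_allele, maf, hwe_p, call_rate.
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", variants = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- object@dosage
    v <- object@variants
    if (ncol(d) != nrow(v))
      msg <- c(msg, "number of dosage columns must equal number of variant rows")
    need <- c("id", "chrom", "pos", "ref", "alt", "minor_allele",
              "maf", "hwe_p", "call_rate")
    if (!all(need %in% names(v)))
      msg <- c(msg, paste("variants table must have columns:",
                          paste(need, collapse = ", ")))
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
      msg <- c(msg, "dosage rows must carry unique sample ids")
    if ("maf" %in% names(v) && any(v$maf > 0.5 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "maf must not exceed 0.5")
    if (all(need %in% names(v))) {
      for (ch in unique(v$chrom)) {
        p <- v$pos[v$chrom == ch]
        if (is.unsorted(p)) {
          msg <- c(msg, "positions must be sorted within chromosome")
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' TaxaProfile: samples x taxa relative abundances
#'
#' Rows are samples, columns taxa; entries are relative abundances in
#' [0, 1] with per-sample sums at most 1 (sums below 1 arise from
#' detection dropout / zero injection). Taxonomy is an optional lineage
#' string per taxon used for genus-level aggregation.
#'
#' @slot abundance numeric matrix in [0,1], samples x taxa.
#' @slot taxonomy named character vector, lineage per taxon id (may be
#'   empty).
#' @aliases TaxaProfile-class
#' @exportClass TaxaProfile
setClass("TaxaProfile",
  representation(abundance = "matrix", taxonomy = "character"),
  validity = function(object) {
    a <- object@abundance
    msg <- character()
    if (any(a < -1e-12 | a > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "abundances must lie in [0, 1]")
    if (any(rowSums(a, na.rm = TRUE) > 1 + 1e-9))
      msg <- c(msg, "per-sample abundance sums must be <= 1")
    if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
      msg <- c(msg, "rows must carry unique sample ids")
    if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
      msg <- c(msg, "columns must carry unique taxon ids")
    if (length(object@taxonomy) &&
        !all(names(object@taxonomy) %in% colnames(a)))
      msg <- c(msg, "taxonomy names must be taxon ids of the profile")
    if (length(msg)) msg else TRUE
  })

#' PreparedTraits: taxa turned into quantitative traits
#'
#' Holds the ln-abundance trait matrix (NA where zero-excluded or
#' outlier-masked), the kept-taxon set after the occurrence/abundance
#' filter, the greedy-selected independent taxa, and per-taxon summary
#' statistics.
#'
#' @slot traits numeric matrix, samples x kept taxa, ln relative abundance
#'   with NA for masked values.
#' @slot keptTaxa character, taxa passing the occurrence/abundance filter.
#' @slot independentTaxa character, greedy dominating-set representatives.
#' @slot stats data.frame with one row per input taxon: occurrence,
#'   mean_abundance, kept, n_outliers_masked, usable.
#' @aliases PreparedTraits-class
#' @exportClass PreparedTraits
setClass("PreparedTraits",
  representation(traits = "matrix", keptTaxa = "character",
                 independentTaxa = "character", stats = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!all(object@independentTaxa %in% object@keptTaxa))
      msg <- c(msg, "independent taxa must be a subset of kept taxa")
    if (!all(colnames(object@traits) %in% object@keptTaxa))
      msg <- c(msg, "trait columns must be kept taxa")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "variants\n")
  v <- object@variants
  cat("  chrom:", paste(unique(v$chrom), collapse = ", "),
      "| MAF range:", sprintf("%.4g-%.4g", min(v$maf), max(v$maf)), "\n")
  invisible(NULL)
})

setMethod("show", "TaxaProfile", function(object) {
  cat("TaxaProfile:", nrow(object@abundance), "samples x",
      ncol(object@abundance), "taxa\n")
  s <- rowSums(object@abundance)
  cat("  per-sample sum range:", sprintf("%.4g-%.4g", min(s), max(s)), "\n")
  invisible(NULL)
})

setMethod("show", "PreparedTraits", function(object) {
  cat("PreparedTraits:", nrow(object@traits), "samples,",
      length(object@keptTaxa), "kept taxa,",
      length(object@independentTaxa), "independent\n")
  invisible(NULL)
})

#' Construct a GenotypeMatrix
#'
#' QC statistics (MAF, HWE chi-square p, call rate) are computed from the
#' dosage matrix; if the allele labelled minor has sample frequency above
#' 0.5 the dosages are complemented and the minor-allele label swapped so
#' that dosage always counts the (in-sample) minor allele.
#'
#' @param dosage samples x variants matrix of alt-allele counts 0/1/2/NA,
#'   with sample ids as rownames.
#' @param variants data.frame with columns id, chrom, pos, ref, alt
#'   (minor_allele optional; defaults to alt before frequency polarisation).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants),
            ncol(dosage) == nrow(variants))
  dosage <- matrix(as.numeric(dosage), nrow = nrow(dosage),
                   dimnames = dimnames(dosage))
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  if (is.null(variants$minor_allele)) variants$minor_allele <- variants$alt
  af <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- which(!is.na(af) & af > 0.5)
  if (length(flip)) {
    dosage[, flip] <- 2 - dosage[, flip]
    other <- ifelse(variants$minor_allele[flip] == variants$alt[flip],
                    variants$ref[flip], variants$alt[flip])
    variants$minor_allele[flip] <- other
  }
  variants$maf <- colMeans(dosage, na.rm = TRUE) / 2
  variants$call_rate <- colMeans(!is.na(dosage))
  variants$hwe_p <- hweChisqVec(dosage)
  rownames(variants) <- NULL
  new("GenotypeMatrix", dosage = dosage, variants = variants)
}

#' Construct a TaxaProfile
#' @param abundance samples x taxa relative-abundance matrix with sample
#'   ids as rownames and taxon ids as colnames.
#' @param taxonomy optional named character vector of lineage strings.
#' @return A \linkS4class{TaxaProfile}.
#' @export
TaxaProfile <- function(abundance, taxonomy = character()) {
  stopifnot(is.matrix(abundance))
  new("TaxaProfile", abundance = abundance, taxonomy = taxonomy)
}

#' @describeIn GenotypeMatrix-class dosage matrix accessor
#' @param x a GenotypeMatrix
#' @export
dosages <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  x@dosage
}

#' @describeIn GenotypeMatrix-class variant metadata accessor
#' @export
variantInfo <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  x@variants
}

#' @describeIn TaxaProfile-class abundance matrix accessor
#' @param x a TaxaProfile
#' @export
abundances <- function(x) {
  stopifnot(is(x, "TaxaProfile"))
  x@abundance
}

#' @describeIn TaxaProfile-class taxonomy accessor
#' @export
taxonomy <- function(x) {
  stopifnot(is(x, "TaxaProfile"))
  x@taxonomy
}

#' Sample identifiers of a container
#' @param x a GenotypeMatrix, TaxaProfile or PreparedTraits
#' @return character vector of sample ids.
#' @export
sampleIds <- function(x) {
  if (is(x, "GenotypeMatrix")) return(rownames(x@dosage))
  if (is(x, "TaxaProfile")) return(rownames(x@abundance))
  if (is(x, "PreparedTraits")) return(rownames(x@traits))
  stop("no sample ids for class ", class(x))
}

#' @describeIn PreparedTraits-class trait matrix accessor
#' @param x a PreparedTraits
#' @export
traitValues <- function(x) {
  stopifnot(is(x, "PreparedTraits"))
  x@traits
}

#' @describeIn PreparedTraits-class kept-taxon accessor
#' @export
keptTaxa <- function(x) {
  stopifnot(is(x, "PreparedTraits"))
  x@keptTaxa
}

#' @describeIn PreparedTraits-class independent-taxon accessor
#' @export
independentTaxa <- function(x) {
  stopifnot(is(x, "PreparedTraits"))
  x@independentTaxa
}

#' @describeIn PreparedTraits-class per-taxon statistics accessor
#' @export
taxonStats <- function(x) {
  stopifnot(is(x, "PreparedTraits"))
  x@stats
}
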