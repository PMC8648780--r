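#' Filter taxa by occurrence and mean abundance
#'
#' A taxon is kept iff its occurrence (fraction of samples with
#' abundance > 0) is at least \code{occurrence_min} and its mean relative
#' abundance (zeros included) is at least \code{abundance_min}. Defaults
#' keep taxa present in at least 90 percent of samples with mean
#' abundance at least 1e-5, the usual prefilter before treating taxa as
#' quantitative traits.
#'
#' @param profile a \linkS4class{TaxaProfile}.
#' @param occurrence_min minimum occurrence fraction.
#' @param abundance_min minimum mean relative abundance.
#' @return data.frame with one row per taxon: taxon, occurrence,
#'   mean_abundance, kept.
#' @export
filterTaxa <- function(profile, occurrence_min = 0.9, abundance_min = 1e-5) {
  a <- abundances(profile)
  if (nrow(a) == 0 || ncol(a) == 0) stop("empty taxa profile")
  occ <- colMeans(a > 0, na.rm = TRUE)
  mn <- colMeans(a, na.rm = TRUE)
  data.frame(taxon = colnames(a), occurrence = occ, mean_abundance = mn,
             kept = occ >= occurrence_min & mn >= abundance_min,
             row.names = NULL)
}

#' Transform abundances into quantitative traits
#'
#' Per kept taxon: zeros are handled by the zero policy, the natural
#' logarithm is applied, and values further than \code{sd_limit}
#' standard deviations from the taxon mean are masked missing in a
#' single pass. Policy \code{"halfmin"} replaces zeros by half the
#' taxon's minimum positive abundance; \code{"missing"} masks them.
#'
#' @param profile a \linkS4class{TaxaProfile}.
#' @param kept_taxa character vector of taxa to transform.
#' @param sd_limit outlier mask threshold in SD units.
#' @param zero_policy "halfmin" or "missing".
#' @return list: \code{traits} (samples x kept taxa ln-abundance matrix
#'   with NAs), \code{n_outliers_masked} and \code{usable} per taxon
#'   (taxa with fewer than 3 usable values are flagged, not dropped).
#' @export
transformAbundance <- function(profile, kept_taxa, sd_limit = 4,
                               zero_policy = c("halfmin", "missing")) {
  zero_policy <- match.arg(zero_policy)
  a <- abundances(profile)
  stopifnot(all(kept_taxa %in% colnames(a)))
  x <- a[, kept_taxa, drop = FALSE]
  out <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  nmask <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    pos <- v[!is.na(v) & v > 0]
    if (zero_policy == "halfmin" && length(pos))
      v[!is.na(v) & v == 0] <- min(pos) / 2
    else v[!is.na(v) & v == 0] <- NA
    lv <- log(v)
    m <- mean(lv, na.rm = TRUE); s <- sd(lv, na.rm = TRUE)
    if (!is.na(s) && s > 0) {
      bad <- !is.na(lv) & abs(lv - m) > sd_limit * s
      nmask[j] <- sum(bad)
      lv[bad] <- NA
    }
    out[, j] <- lv
  }
  usable <- colSums(!is.na(out)) >= 3
  list(traits = out,
       n_outliers_masked = setNames(nmask, colnames(x)),
       usable = setNames(usable, colnames(x)))
}

#' Build the taxon Spearman correlation graph
#'
#' Pairwise Spearman correlations (average ranks for ties, pairwise
#' complete observations) between taxa; an edge joins a pair whose
#' correlation exceeds the threshold — \code{|rho| > threshold} in mode
#' \code{raw_rho}, \code{rho^2 > threshold} in mode \code{squared}.
#'
#' @param traits samples x taxa matrix (any monotone scale; Spearman is
#'   rank-invariant).
#' @param threshold edge threshold, default 0.8.
#' @param mode "raw_rho" or "squared".
#' @param min_pairs minimum pairwise-complete samples; pairs below it are
#'   skipped (no edge) and counted.
#' @return list of class \code{mgwasTaxonGraph}: nodes, edges data.frame
#'   (i, j, rho), threshold, mode, n_skipped_pairs.
#' @export
buildCorrelationGraph <- function(traits, threshold = 0.8,
                                  mode = c("raw_rho", "squared"),
                                  min_pairs = 5) {
  mode <- match.arg(mode)
  stopifnot(ncol(traits) >= 2)
  rho <- suppressWarnings(cor(traits, method = "spearman",
                              use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(traits))
  nodes <- colnames(traits)
  up <- upper.tri(rho)
  enough <- npair >= min_pairs
  skip <- sum(up & !enough)
  hit <- if (mode == "raw_rho") abs(rho) > threshold else rho^2 > threshold
  sel <- which(up & enough & !is.na(rho) & hit, arr.ind = TRUE)
  edges <- data.frame(i = nodes[sel[, 1]], j = nodes[sel[, 2]],
                      rho = rho[sel])
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 mode = mode, n_skipped_pairs = skip),
            class = "mgwasTaxonGraph")
}

#' @export
print.mgwasTaxonGraph <- function(x, ...) {
  cat("taxon correlation graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (", x$mode, ">", x$threshold, ")\n")
  invisible(x)
}

#' Greedy selection of independent taxa
#'
#' Repeatedly picks the node of highest degree in the current graph
#' (ties broken at random under the given seed, or lexicographically),
#' adds it to the selection, and removes it together with all its
#' current neighbours, until the graph is empty. Isolated nodes are all
#' selected. The result is an independent dominating set of the input
#' graph: no two selected taxa are adjacent, and every discarded taxon
#' is adjacent to at least one selected taxon.
#'
#' @param graph an \code{mgwasTaxonGraph}.
#' @param tie_break "random" (seeded) or "lexicographic".
#' @param seed seed for random tie-breaking.
#' @return character vector of selected taxon ids (input node order).
#' @export
greedySelectIndependent <- function(graph, tie_break = c("random",
                                                         "lexicographic"),
                                    seed = 1L) {
  tie_break <- match.arg(tie_break)
  nodes <- graph$nodes
  adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                function(x) character())
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    if (i == j) next
    adj[[i]] <- union(adj[[i]], j)
    adj[[j]] <- union(adj[[j]], i)
  }
  alive <- setNames(rep(TRUE, length(nodes)), nodes)
  selected <- character()
  pick <- function(cands) {
    if (length(cands) == 1) return(cands)
    if (tie_break == "lexicographic") sort(cands)[1]
    else cands[sample.int(length(cands), 1)]
  }
  withSubSeed(seed, "greedy", {
    while (any(alive)) {
      deg <- vapply(names(alive)[alive],
                    function(v) sum(alive[adj[[v]]]), numeric(1))
      top <- names(deg)[deg == max(deg)]
      v <- pick(top)
      selected <- c(selected, v)
      alive[v] <- FALSE
      alive[adj[[v]][alive[adj[[v]]]]] <- FALSE
    }
  })
  nodes[nodes %in% selected]
}

#' Prepare taxa for association scanning
#'
#' Runs the full taxon-preparation chain: occurrence/abundance filter,
#' ln transform with outlier masking, Spearman correlation graph, and
#' greedy independent-taxon selection.
#'
#' @inheritParams filterTaxa
#' @inheritParams transformAbundance
#' @inheritParams buildCorrelationGraph
#' @inheritParams greedySelectIndependent
#' @return A \linkS4class{PreparedTraits}.
#' @export
prepareTaxa <- function(profile, occurrence_min = 0.9, abundance_min = 1e-5,
                        sd_limit = 4, zero_policy = "halfmin",
                        threshold = 0.8, mode = "raw_rho",
                        tie_break = "random", seed = 1L) {
  fs <- filterTaxa(profile, occurrence_min, abundance_min)
  kept <- fs$taxon[fs$kept]
  if (length(kept) == 0) stop("no taxa pass the occurrence/abundance filter")
  tr <- transformAbundance(profile, kept, sd_limit, zero_policy)
  usable <- names(tr$usable)[tr$usable]
  indep <- if (length(usable) >= 2) {
    # correlations on raw relative abundance; Spearman is invariant to
    # the monotone ln for complete observations
    g <- buildCorrelationGraph(abundances(profile)[, usable, drop = FALSE],
                               threshold = threshold, mode = mode)
    greedySelectIndependent(g, tie_break = tie_break, seed = seed)
  } else usable
  st <- fs
  st$n_outliers_masked <- ifelse(st$taxon %in% kept,
                                 tr$n_outliers_masked[st$taxon], NA)
  st$usable <- ifelse(st$taxon %in% kept, tr$usable[st$taxon], FALSE)
  new("PreparedTraits", traits = tr$traits, keptTaxa = kept,
      independentTaxa = indep, stats = st)
}
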