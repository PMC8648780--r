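# Shared fixture builders; everything is generated in code at test time.

# Minimal GenotypeMatrix from a bare dosage matrix.
makeGenotypes <- function(dosage, chrom = NULL, pos = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%03d", seq_len(n))
  ids <- colnames(dosage)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  colnames(dosage) <- ids
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  GenotypeMatrix(dosage, data.frame(id = ids, chrom = chrom, pos = pos,
                                    ref = rep("A", m), alt = rep("G", m)))
}

# Random HWE dosage matrix at given MAFs.
randomDosage <- function(n, mafs) {
  m <- length(mafs)
  d <- vapply(mafs, function(p) rbinom(n, 2, p), numeric(n))
  colnames(d) <- sprintf("v%03d", seq_len(m))
  rownames(d) <- sprintf("s%03d", seq_len(n))
  d
}

# Random Erdos-Renyi graph in the package's edge-list shape.
randomGraph <- function(n_nodes, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < p_edge
  structure(list(nodes = nodes,
                 edges = data.frame(i = nodes[pairs[on, 1]],
                                    j = nodes[pairs[on, 2]],
                                    rho = rep(0.9, sum(on))),
                 threshold = 0.8, mode = "raw_rho", n_skipped_pairs = 0L),
            class = "mgwasTaxonGraph")
}

# Brute-force check that `sel` is an independent dominating set of the
# graph (adjacency checked pairwise; domination checked per node).
checkIndependentDominating <- function(graph, sel) {
  adj <- matrix(FALSE, length(graph$nodes), length(graph$nodes),
                dimnames = list(graph$nodes, graph$nodes))
  for (k in seq_len(nrow(graph$edges))) {
    adj[graph$edges$i[k], graph$edges$j[k]] <- TRUE
    adj[graph$edges$j[k], graph$edges$i[k]] <- TRUE
  }
  indep <- all(!adj[sel, sel, drop = FALSE])
  others <- setdiff(graph$nodes, sel)
  dom <- all(vapply(others, function(v) any(adj[v, sel]), logical(1)))
  indep && dom
}

# Spearman's rho by the explicit rank-Pearson formula (average ranks),
# independent of stats::cor(method = "spearman").
spearmanOracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small cohort for integration-style tests.
smallCohort <- function(seed = 1, ...) {
  simulateCohort(simulationConfig(n_discovery = 300, n_replication = 200,
                                  n_snps = 150, n_taxa = 20, n_planted = 3,
                                  n_clusters = 2, cluster_size = 3,
                                  n_env = 8, n_collinear_pairs = 2,
                                  seed = seed, ...))
}
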