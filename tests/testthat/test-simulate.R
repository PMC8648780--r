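test_that("genotype generator is HWE-calibrated at the requested MAF", {
  cfg <- simulationConfig(n_discovery = 10000, n_replication = 0,
                          n_snps = 200, maf_range = c(0.3, 0.3),
                          ld_copy_prob = 0, n_subpops = 1, seed = 5)
  g <- simulateGenotypes(cfg, 10000)
  v <- variantInfo(g)
  expect_true(all(abs(v$maf - 0.3) < 0.02))
  exact_p <- apply(dosages(g)[, 1:100], 2,
                   function(x) mgwas:::hweExactTest(x)$p)
  expect_gte(mean(exact_p > 1e-5), 0.99)
})

test_that("full haplotype copying makes adjacent SNPs perfectly correlated", {
  cfg <- simulationConfig(n_discovery = 200, n_replication = 0,
                          n_snps = 20, ld_copy_prob = 1, seed = 6)
  g <- simulateGenotypes(cfg, 200)
  d <- dosages(g)
  r2 <- vapply(1:19, function(j) cor(d[, j], d[, j + 1])^2, numeric(1))
  expect_true(all(r2 > 1 - 1e-12))
})

test_that("zero divergence leaves two subpopulations indistinguishable", {
  cfg <- simulationConfig(n_discovery = 4000, n_replication = 0,
                          n_snps = 300, n_subpops = 2, fst = 0, seed = 7)
  g <- simulateGenotypes(cfg, 4000)
  sp <- attr(g, "subpop")
  d <- dosages(g)
  f1 <- colMeans(d[sp == 1, ]) / 2
  f2 <- colMeans(d[sp == 2, ]) / 2
  # difference of two binomial frequency estimates, ~N(0, 2 p q / n_hap)
  se <- sqrt(2 * f1 * (1 - f1) / (2 * 2000))
  expect_lt(mean(abs(f1 - f2) > 4 * se), 0.01)
})

test_that("population structure is visible on the leading genotype PC", {
  cfg <- simulationConfig(n_discovery = 1000, n_replication = 0,
                          n_snps = 5000, n_subpops = 2, fst = 0.1,
                          seed = 3)
  g <- simulateGenotypes(cfg, 1000)
  pc <- genotypePCs(g, 2)
  expect_gt(abs(cor(pc[, 1], attr(g, "subpop"))), 0.9)
})

test_that("relative abundances sum to one before zero injection, at most one after", {
  co0 <- simulateCohort(simulationConfig(n_discovery = 150,
                                         n_replication = 0, n_snps = 60,
                                         n_taxa = 25, zero_inflation = 0,
                                         seed = 8, n_planted = 3))
  expect_true(all(abs(rowSums(abundances(co0$discovery$taxa)) - 1) < 1e-9))
  co1 <- simulateCohort(simulationConfig(n_discovery = 150,
                                         n_replication = 0, n_snps = 60,
                                         n_taxa = 25, zero_inflation = 0.2,
                                         seed = 8, n_planted = 3))
  s <- rowSums(abundances(co1$discovery$taxa))
  expect_true(all(s <= 1 + 1e-9))
  expect_true(any(abundances(co1$discovery$taxa) == 0))
})

test_that("planted effects are recovered within 3 SE of truth across seeds", {
  hits <- vapply(1:50, function(s) {
    co <- simulateCohort(simulationConfig(n_discovery = 400,
                                          n_replication = 0, n_snps = 60,
                                          n_taxa = 20, n_planted = 2,
                                          n_clusters = 0,
                                          zero_inflation = 0, n_env = 0,
                                          n_collinear_pairs = 0,
                                          seed = 1000 + s))
    pa <- co$truth$planted_associations
    a <- abundances(co$discovery$taxa)
    v <- variantInfo(co$discovery$genotypes)
    d <- dosages(co$discovery$genotypes)
    ok <- vapply(seq_len(nrow(pa)), function(i) {
      j <- match(pa$snp_id[i], v$id)
      x <- if (v$minor_allele[j] == v$alt[j]) d[, j] else 2 - d[, j]
      f <- summary(lm(log(a[, pa$taxon_id[i]]) ~ x))$coefficients
      abs(f["x", "Estimate"] - pa$beta[i]) < 3 * f["x", "Std. Error"]
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a tight taxon cluster forms a connected block in the correlation graph", {
  co <- simulateCohort(simulationConfig(n_discovery = 500,
                                        n_replication = 0, n_snps = 50,
                                        n_taxa = 30, n_clusters = 1,
                                        cluster_size = 5,
                                        cluster_rho = 0.95, n_planted = 0,
                                        zero_inflation = 0, n_env = 0,
                                        n_collinear_pairs = 0, seed = 4))
  a <- abundances(co$discovery$taxa)
  gr <- buildCorrelationGraph(a, threshold = 0.8)
  block <- colnames(a)[1:5]
  within <- sum(gr$edges$i %in% block & gr$edges$j %in% block)
  expect_gte(within, 4)  # at least a spanning set of edges
})

test_that("without planted structure no taxon pair crosses the edge threshold", {
  co <- simulateCohort(simulationConfig(n_discovery = 1000,
                                        n_replication = 0, n_snps = 50,
                                        n_taxa = 20, n_planted = 0,
                                        n_clusters = 0, zero_inflation = 0,
                                        n_env = 0, n_collinear_pairs = 0,
                                        seed = 9))
  gr <- buildCorrelationGraph(abundances(co$discovery$taxa), 0.8)
  expect_equal(nrow(gr$edges), 0)
})

test_that("disease prevalence matches target and null disease is unpredictable", {
  co <- simulateCohort(simulationConfig(n_discovery = 5000,
                                        n_replication = 0, n_snps = 50,
                                        n_taxa = 10, n_planted = 0,
                                        disease_prevalence = 0.2,
                                        seed = 10))
  prev <- mean(co$discovery$phenotypes$disease)
  expect_gte(prev, 0.18); expect_lte(prev, 0.22)

  # all liability weights zero: outcome independent of genotype
  co0 <- simulateCohort(simulationConfig(n_discovery = 2000,
                                         n_replication = 0, n_snps = 50,
                                         n_taxa = 10, n_planted = 0,
                                         disease_snp_weight = 0,
                                         disease_microbiome_weight = 0,
                                         seed = 11))
  gscore <- rowSums(dosages(co0$discovery$genotypes))
  auc <- mgwas:::rankAuc(gscore, co0$discovery$phenotypes$disease)
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("simulation is deterministic under the master seed and substreams are stable", {
  cfg <- simulationConfig(n_discovery = 120, n_replication = 80,
                          n_snps = 40, n_taxa = 10, n_planted = 2, seed = 12)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(dosages(a$discovery$genotypes),
                   dosages(b$discovery$genotypes))
  expect_identical(abundances(a$replication$taxa),
                   abundances(b$replication$taxa))
})

test_that("configuration validation rejects invalid settings", {
  expect_error(simulationConfig(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(simulationConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulationConfig(zero_inflation = 1.2), "zero_inflation")
  expect_error(simulationConfig(n_subpops = 3), "n_subpops")
  expect_error(
    simulateCohort(simulationConfig(n_discovery = 100, n_snps = 20,
                                    n_taxa = 5, n_planted = 10,
                                    n_replication = 0)),
    "planted")
})
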