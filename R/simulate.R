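#' Simulation configuration for synthetic mgGWAS cohorts
#'
#' Defines the study conditions for the bundled cohort generator: a
#' discovery and a replication cohort drawn on a shared biallelic SNP
#' panel, taxon relative-abundance profiles whose log scale carries
#' planted additive SNP effects and environmental effects, correlated
#' taxon clusters, per-taxon zero inflation, collinear environmental
#' covariates, and liability-threshold binary diseases.
#'
#' Defaults describe a desk-scale cohort: 2000 discovery and 1000
#' replication individuals, 5000 SNPs with MAF drawn in (0.05, 0.5), 50
#' taxa of which 5 clusters of 4 share a latent factor at correlation
#' 0.6, 20 planted SNP-taxon pairs with per-allele effects in
#' [0.5, 1.0] on the ln-abundance scale restricted to SNPs with MAF at
#' least 0.1, 5 percent zero inflation, 20 environmental covariates with
#' 4 collinear pairs, and a 20 percent prevalence disease driven by 10
#' SNPs plus a microbiome component.
#'
#' @param n_discovery,n_replication cohort sizes.
#' @param n_snps number of biallelic SNPs on the shared panel.
#' @param maf_range length-2 numeric in (0, 0.5], range of panel minor
#'   allele frequencies.
#' @param ld_copy_prob probability that a haplotype copies its previous
#'   SNP's allele (first-order Markov LD along each chromosome).
#' @param snps_per_chrom panel SNPs per synthetic chromosome.
#' @param n_subpops 1 or 2 subpopulations.
#' @param fst Balding-Nichols divergence between subpopulations.
#' @param n_taxa,n_clusters,cluster_size,cluster_rho taxon panel: total
#'   taxa, number of correlated clusters, taxa per cluster, and target
#'   within-cluster latent correlation.
#' @param zero_inflation per-taxon probability of zeroing an observation
#'   after renormalisation (detection dropout).
#' @param n_planted number of causal SNP-taxon pairs.
#' @param effect_size_range per-minor-allele additive effect range on ln
#'   abundance.
#' @param planted_maf_min minimum MAF for SNPs eligible to carry a
#'   planted effect.
#' @param n_env number of environmental covariates.
#' @param n_collinear_pairs number of env pairs constructed with
#'   absolute correlation above 0.6.
#' @param env_effect_size effect of each active env covariate on its
#'   target taxa's ln abundance.
#' @param disease_prevalence target case fraction.
#' @param n_disease_snps number of SNPs with liability weights.
#' @param disease_snp_weight liability weight per disease SNP.
#' @param disease_microbiome_weight liability weight of the standardized
#'   mean ln abundance of the microbiome score taxa.
#' @param disease_noise_sd sd of the liability noise term.
#' @param seed master seed; every stage draws from a named substream.
#' @return A classed list of validated settings.
#' @export
simulationConfig <- function(n_discovery = 2000, n_replication = 1000,
                             n_snps = 5000, maf_range = c(0.05, 0.5),
                             ld_copy_prob = 0, snps_per_chrom = 500,
                             n_subpops = 1, fst = 0,
                             n_taxa = 50, n_clusters = 5, cluster_size = 4,
                             cluster_rho = 0.6, zero_inflation = 0.05,
                             n_planted = 20, effect_size_range = c(0.5, 1.0),
                             planted_maf_min = 0.1,
                             n_env = 20, n_collinear_pairs = 4,
                             env_effect_size = 0.3,
                             disease_prevalence = 0.2, n_disease_snps = 10,
                             disease_snp_weight = 0.3,
                             disease_microbiome_weight = 0.5,
                             disease_noise_sd = 1,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_discovery", "n_replication", "n_snps", "n_taxa",
              "n_clusters", "cluster_size", "n_planted", "n_env",
              "n_collinear_pairs", "n_disease_snps", "snps_per_chrom")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("configuration error: ", f, " must be a non-negative count")
  probs <- c("ld_copy_prob", "zero_inflation", "disease_prevalence")
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("configuration error: maf_range must be increasing within (0, 0.5]")
  if (length(cfg$effect_size_range) != 2 ||
      cfg$effect_size_range[1] > cfg$effect_size_range[2])
    stop("configuration error: effect_size_range must be ordered")
  if (!n_subpops %in% 1:2)
    stop("configuration error: n_subpops must be 1 or 2")
  if (fst < 0) stop("configuration error: fst must be >= 0")
  structure(cfg, class = "mgwasSimulationConfig")
}

#' @export
print.mgwasSimulationConfig <- function(x, ...) {
  cat("mgGWAS simulation config:",
      x$n_discovery, "+", x$n_replication, "samples,",
      x$n_snps, "SNPs,", x$n_taxa, "taxa,",
      x$n_planted, "planted pairs, seed", x$seed, "\n")
  invisible(x)
}

# Draw the shared SNP panel: chrom/pos/alleles and per-subpopulation
# allele frequencies (Balding-Nichols under fst > 0).
simulatePanel <- function(config) {
  withSubSeed(config$seed, "panel", {
    m <- config$n_snps
    per <- config$snps_per_chrom
    chrom <- paste0("chr", rep(seq_len(ceiling(m / per)), each = per)[seq_len(m)])
    pos <- unlist(lapply(split(seq_len(m), chrom)[unique(chrom)],
                         function(ix) cumsum(sample(5000:15000, length(ix),
                                                    replace = TRUE))),
                  use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    p0 <- runif(m, config$maf_range[1], config$maf_range[2])
    freq <- matrix(p0, nrow = m, ncol = config$n_subpops)
    if (config$n_subpops == 2 && config$fst > 0) {
      a <- p0 * (1 - config$fst) / config$fst
      b <- (1 - p0) * (1 - config$fst) / config$fst
      freq[, 1] <- stats::rbeta(m, a, b)
      freq[, 2] <- stats::rbeta(m, a, b)
    }
    data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = chrom, pos = pos,
               ref = ref, alt = alt, freq, check.names = FALSE) ->
      panel
    names(panel)[6:(5 + config$n_subpops)] <-
      paste0("af", seq_len(config$n_subpops))
    panel
  })
}

#' Simulate cohort genotypes on a shared SNP panel
#'
#' Within each subpopulation genotypes are Hardy-Weinberg draws from the
#' panel allele frequency. Linkage disequilibrium is induced by
#' first-order haplotype copying: each haplotype repeats its previous
#' SNP's allele with probability \code{ld_copy_prob}, otherwise draws
#' fresh from the allele frequency; chains restart at chromosome starts.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param n number of individuals.
#' @param panel panel data.frame from the internal panel draw; supplied
#'   by \code{\link{simulateCohort}} so both cohorts share positions,
#'   alleles and frequencies. Defaults to a fresh draw.
#' @param stream substream name (keeps discovery/replication independent).
#' @param prefix sample-id prefix.
#' @return A \linkS4class{GenotypeMatrix}; with two subpopulations the
#'   assignment is stored in \code{attr(, "subpop")}.
#' @export
simulateGenotypes <- function(config, n = config$n_discovery,
                              panel = simulatePanel(config),
                              stream = "genotypes", prefix = "S") {
  stopifnot(config$n_snps >= 1, n >= 2)
  m <- nrow(panel)
  withSubSeed(config$seed, stream, {
    subpop <- if (config$n_subpops == 2)
      sample(rep(1:2, length.out = n)) else rep(1L, n)
    hap <- function() {
      h <- matrix(0L, n, m)
      pfreq <- as.matrix(panel[, paste0("af", seq_len(config$n_subpops)),
                               drop = FALSE])
      newchrom <- c(TRUE, panel$chrom[-1] != panel$chrom[-m])
      p <- pfreq[cbind(rep(seq_len(m), each = n), rep(subpop, m))]
      fresh <- matrix(runif(n * m) < p, n, m)
      if (config$ld_copy_prob <= 0) return(fresh + 0L)
      copy <- matrix(runif(n * m) < config$ld_copy_prob, n, m)
      h[, 1] <- fresh[, 1]
      for (j in 2:m) {
        h[, j] <- if (newchrom[j]) fresh[, j]
                  else ifelse(copy[, j], h[, j - 1], fresh[, j])
      }
      h
    }
    d <- hap() + hap()
    rownames(d) <- sprintf("%s%05d", prefix, seq_len(n))
    colnames(d) <- panel$id
    g <- GenotypeMatrix(d, panel[, c("id", "chrom", "pos", "ref", "alt")])
    attr(g, "subpop") <- subpop
    g
  })
}

#' Simulate environmental covariates
#'
#' Half the covariates are continuous (standard normal), half binary;
#' the first \code{n_collinear_pairs} continuous variables each get a
#' collinear partner constructed at correlation about 0.8, emulating
#' redundant questionnaire/serum measurements.
#'
#' @inheritParams simulateGenotypes
#' @return data.frame of covariates with sample ids as rownames.
#' @export
simulateCovariates <- function(config, n = config$n_discovery,
                               stream = "covariates", prefix = "S") {
  withSubSeed(config$seed, stream, {
    k <- config$n_env
    x <- matrix(rnorm(n * k), n, k)
    kc <- max(0, min(config$n_collinear_pairs, floor(k / 2)))
    if (kc > 0) {
      for (j in seq_len(kc)) {
        a <- 2 * j - 1
        x[, 2 * j] <- 0.8 * x[, a] + sqrt(1 - 0.64) * rnorm(n)
      }
    }
    nbin <- floor((k - 2 * kc) / 2)
    if (nbin > 0) {
      bcols <- (k - nbin + 1):k
      x[, bcols] <- (x[, bcols] > qnorm(0.7)) + 0
    }
    colnames(x) <- sprintf("env%02d", seq_len(k))
    rownames(x) <- sprintf("%s%05d", prefix, seq_len(n))
    as.data.frame(x)
  })
}

# Draw the ground truth: planted SNP-taxon effects, env-taxon effects,
# disease liability weights and microbiome score taxa. One draw per
# cohort pair (shared by discovery and replication).
simulateTruth <- function(config, panel) {
  withSubSeed(config$seed, "truth", {
    taxa <- sprintf("t%04d", seq_len(config$n_taxa))
    maf0 <- pmin(panel$af1, 1 - panel$af1)
    eligible <- panel$id[maf0 >= config$planted_maf_min]
    if (config$n_planted > length(eligible))
      stop("not enough SNPs above planted_maf_min for planted effects")
    if (config$n_planted > config$n_taxa)
      stop("n_planted must not exceed n_taxa (one planted SNP per taxon)")
    ps <- sample(eligible, config$n_planted)
    pt <- sample(taxa, config$n_planted)
    planted <- data.frame(snp_id = ps, taxon_id = pt,
                          beta = runif(config$n_planted,
                                       config$effect_size_range[1],
                                       config$effect_size_range[2]))
    n_active_env <- min(config$n_env, max(0, ceiling(config$n_env / 4)))
    env_effects <- if (n_active_env > 0)
      data.frame(env_id = sprintf("env%02d", seq_len(n_active_env)),
                 taxon_id = sample(taxa, n_active_env, replace = TRUE),
                 gamma = config$env_effect_size)
    else data.frame(env_id = character(), taxon_id = character(),
                    gamma = numeric())
    dsnp <- sample(setdiff(panel$id[maf0 >= 0.1], ps),
                   min(config$n_disease_snps, sum(maf0 >= 0.1)))
    disease_weights <- data.frame(snp_id = dsnp,
                                  weight = config$disease_snp_weight)
    score_taxa <- sample(taxa, min(5, config$n_taxa))
    list(planted_associations = planted, env_effects = env_effects,
         disease_weights = disease_weights,
         disease_microbiome_score_taxa = score_taxa)
  })
}

#' Simulate a taxon relative-abundance profile with planted effects
#'
#' Latent per-taxon ln abundance is
#' \code{z = mu + beta * dosage + gamma * env + cluster factor + noise};
#' relative abundances are \code{exp(z)} renormalised per sample to sum
#' to one, after which zeros are injected per taxon with probability
#' \code{zero_inflation} (no re-normalisation, mimicking detection
#' dropout).
#'
#' @inheritParams simulateGenotypes
#' @param genotypes \linkS4class{GenotypeMatrix} for the cohort.
#' @param env covariate data.frame for the same samples.
#' @param truth truth list from the cohort draw (planted effects).
#' @return A \linkS4class{TaxaProfile}; genus lineages group every 5
#'   consecutive taxa so genus-level aggregation is exercised.
#' @export
simulateTaxa <- function(config, genotypes, env, truth,
                         stream = "taxa") {
  d <- dosages(genotypes)
  stopifnot(identical(rownames(d), rownames(env)))
  n <- nrow(d); T <- config$n_taxa
  taxa <- sprintf("t%04d", seq_len(T))
  miss <- setdiff(truth$planted_associations$snp_id, colnames(d))
  if (length(miss))
    stop("planted pair references missing SNP: ", paste(miss, collapse = ","))
  if (!all(truth$planted_associations$taxon_id %in% taxa))
    stop("planted pair references missing taxon")
  withSubSeed(config$seed, stream, {
    mu <- rnorm(T, 0, 1)
    z <- matrix(rnorm(n * T), n, T) + rep(mu, each = n)
    # correlated clusters share a latent factor; loading chosen so the
    # within-cluster latent correlation equals cluster_rho
    if (config$n_clusters > 0 && config$cluster_size > 1 &&
        config$cluster_rho > 0) {
      lam <- sqrt(config$cluster_rho / (1 - config$cluster_rho))
      for (c in seq_len(config$n_clusters)) {
        cols <- ((c - 1) * config$cluster_size + 1):(c * config$cluster_size)
        cols <- cols[cols <= T]
        if (length(cols) < 2) next
        f <- rnorm(n)
        z[, cols] <- z[, cols] + lam * f
      }
    }
    # planted betas are defined per copy of the panel ALT allele so the
    # same physical effect is applied in every cohort regardless of which
    # allele happens to be minor in-sample
    vi <- variantInfo(genotypes)
    pa <- truth$planted_associations
    for (i in seq_len(nrow(pa))) {
      tcol <- match(pa$taxon_id[i], taxa)
      j <- match(pa$snp_id[i], vi$id)
      altdos <- if (vi$minor_allele[j] == vi$alt[j]) d[, j] else 2 - d[, j]
      z[, tcol] <- z[, tcol] + pa$beta[i] * altdos
    }
    ee <- truth$env_effects
    for (i in seq_len(nrow(ee))) {
      tcol <- match(ee$taxon_id[i], taxa)
      x <- env[[ee$env_id[i]]]
      if (sd(x) > 0) x <- (x - mean(x)) / sd(x)
      z[, tcol] <- z[, tcol] + ee$gamma[i] * x
    }
    a <- exp(z)
    a <- a / rowSums(a)
    if (config$zero_inflation > 0) {
      drop <- matrix(runif(n * T) < config$zero_inflation, n, T)
      a[drop] <- 0
    }
    dimnames(a) <- list(rownames(d), taxa)
    lineage <- setNames(paste0("k__Bacteria|g__genus",
                               sprintf("%03d", (seq_len(T) - 1) %/% 5 + 1),
                               "|s__", taxa), taxa)
    TaxaProfile(a, lineage)
  })
}

#' Simulate liability-threshold binary diseases
#'
#' Liability is the weighted dosage sum over the disease SNPs plus
#' \code{disease_microbiome_weight} times the standardized mean ln
#' abundance of the microbiome score taxa plus Gaussian noise; cases are
#' the samples above the (1 - prevalence) empirical liability quantile.
#'
#' @inheritParams simulateTaxa
#' @param taxa \linkS4class{TaxaProfile} for the cohort.
#' @return data.frame with column \code{disease} (0/1) and the latent
#'   \code{liability}, sample ids as rownames.
#' @export
simulateDisease <- function(config, genotypes, taxa, truth,
                            stream = "disease") {
  stopifnot(config$disease_prevalence > 0, config$disease_prevalence < 1)
  d <- dosages(genotypes)
  a <- abundances(taxa)
  withSubSeed(config$seed, stream, {
    g <- if (nrow(truth$disease_weights)) {
      vi <- variantInfo(genotypes)
      j <- match(truth$disease_weights$snp_id, vi$id)
      dd <- d[, j, drop = FALSE]
      flip <- vi$minor_allele[j] != vi$alt[j]
      if (any(flip)) dd[, flip] <- 2 - dd[, flip]
      as.vector(dd %*% truth$disease_weights$weight)
    } else rep(0, nrow(d))
    st <- truth$disease_microbiome_score_taxa
    lo <- log(pmax(a[, st, drop = FALSE], 1e-12))
    mscore <- rowMeans(lo)
    if (sd(mscore) > 0) mscore <- (mscore - mean(mscore)) / sd(mscore)
    liab <- g + config$disease_microbiome_weight * mscore +
      rnorm(nrow(d), 0, config$disease_noise_sd)
    thr <- quantile(liab, 1 - config$disease_prevalence, names = FALSE)
    out <- data.frame(disease = as.integer(liab > thr), liability = liab)
    rownames(out) <- rownames(d)
    out
  })
}

#' Simulate a full two-cohort study
#'
#' Draws one SNP panel and one ground truth, then a discovery and a
#' replication cohort on that shared panel, each with genotypes,
#' covariates, a taxon profile carrying the same planted effects, and a
#' liability-threshold disease phenotype.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{discovery} and \code{replication}
#'   (each: genotypes, taxa, covariates, phenotypes), \code{truth},
#'   \code{panel} and \code{config}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  panel <- simulatePanel(config)
  truth <- simulateTruth(config, panel)
  one <- function(n, stream, prefix) {
    g <- simulateGenotypes(config, n, panel,
                           stream = paste0("genotypes.", stream),
                           prefix = prefix)
    env <- simulateCovariates(config, n,
                              stream = paste0("covariates.", stream),
                              prefix = prefix)
    tp <- simulateTaxa(config, g, env, truth,
                       stream = paste0("taxa.", stream))
    ph <- simulateDisease(config, g, tp, truth,
                          stream = paste0("disease.", stream))
    list(genotypes = g, taxa = tp, covariates = env, phenotypes = ph)
  }
  disc <- one(config$n_discovery, "discovery", "D")
  repl <- if (config$n_replication > 0)
    one(config$n_replication, "replication", "R") else NULL
  list(discovery = disc, replication = repl, truth = truth,
       panel = panel, config = config)
}
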