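#' Run the full mgGWAS pipeline on a simulated or supplied cohort
#'
#' Orchestrates the stages in order: taxon preparation (filter, ln
#' transform, greedy independent-taxon selection), variant QC and
#' genotype PCs, per-taxon linear scans with genomic-inflation
#' diagnostics, alpha-diversity scan, two-axis beta-diversity MANOVA
#' scan, clumping into independent associations and loci, cross-cohort
#' replication with resampling enrichment, environmental dbRDA variance
#' partitioning, and PRS-based disease prediction. Writes stage outputs
#' as TSV/JSON under \code{outdir} together with a manifest.
#'
#' @param cohort a cohort list from \code{\link{simulateCohort}} (or of
#'   the same shape built from files via the readers).
#' @param outdir output directory, or NULL to skip writing.
#' @param scan_cfg a \code{\link{scanConfig}}.
#' @param prs_cfg a \code{\link{prsConfig}} (NULL skips the PRS stage).
#' @param n_perm permutations for the env dbRDA stage.
#' @param seed master seed for the randomized stages.
#' @return list with per-stage results: prepared, qc, scans (per-trait
#'   association tables), lambda (per trait), thresholds, clumps,
#'   replication, env, prs.
#' @export
runPipeline <- function(cohort, outdir = NULL, scan_cfg = scanConfig(),
                        prs_cfg = prsConfig(), n_perm = 199, seed = 1L) {
  disc <- cohort$discovery
  prep <- prepareTaxa(disc$taxa, seed = seed)
  qc <- variantQC(disc$genotypes, scan_cfg)
  g <- subsetVariants(disc$genotypes, qc$id[qc$pass])
  pcs <- genotypePCs(g, scan_cfg$n_pcs)
  covars <- cbind(pcs)
  traits <- traitValues(prep)[, independentTaxa(prep), drop = FALSE]
  scans <- lapply(colnames(traits), function(tx)
    linearScan(g, traits[, tx], covars, scan_cfg, trait_id = tx))
  names(scans) <- colnames(traits)
  all_assoc <- do.call(rbind, scans)
  rownames(all_assoc) <- NULL
  lambda <- vapply(scans, function(s) genomicInflation(p = s$p), numeric(1))
  thr <- significanceThresholds(scan_cfg$gw_alpha, ncol(traits))
  gw <- all_assoc[!is.na(all_assoc$p) & all_assoc$p < thr$genome_wide, ,
                  drop = FALSE]
  clump_assoc <- clumpAssociations(gw, g, scan_cfg, scope = "per_trait")
  clump_loci <- clumpAssociations(gw, g, scan_cfg, scope = "variants")
  # diversity traits
  shannon <- alphaDiversity(disc$taxa)
  alpha_scan <- linearScan(g, shannon, covars, scan_cfg,
                           trait_id = "shannon")
  bc <- brayCurtis(disc$taxa)
  ord <- pcoa(bc, n_axes = 2)
  beta_scan <- betaDiversityScan(g, ord$axes, covars, scan_cfg)
  # replication: full same-trait scan in the second cohort; the
  # resampling pool for the expected rate is the whole tested universe
  # of (variant, trait) pairs, so chance replication dominates it
  replication <- NULL
  if (!is.null(cohort$replication)) {
    rg <- subsetVariants(cohort$replication$genotypes,
                         intersect(qc$id[qc$pass],
                                   variantInfo(cohort$replication$genotypes)$id))
    rep_taxa <- intersect(independentTaxa(prep),
                          colnames(abundances(cohort$replication$taxa)))
    rep_prep <- transformAbundance(cohort$replication$taxa, rep_taxa)
    rpcs <- genotypePCs(rg, scan_cfg$n_pcs)
    rep_scans <- lapply(rep_taxa, function(tx)
      linearScan(rg, rep_prep$traits[, tx], rpcs, scan_cfg, trait_id = tx))
    rep_assoc <- do.call(rbind, rep_scans)
    replication <- replicatePairs(gw, all_assoc, rep_assoc,
                                  variantInfo(g), variantInfo(rg),
                                  seed = seed)
  }
  # environment stage
  env_scan <- NULL
  pruned <- pruneCollinearEnv(disc$covariates)
  if (length(pruned$kept) >= 1) {
    env_scan <- dbrdaEnvScan(bc, disc$covariates[, pruned$kept,
                                                 drop = FALSE],
                             n_perm = n_perm, seed = seed)
    env_scan$pruned <- pruned
    env_scan$variance <- geneticsVsEnvVariance(bc, g, beta_scan, env_scan,
                                               disc$covariates)
  }
  # PRS stage
  prs <- NULL
  if (!is.null(prs_cfg) && !is.null(disc$phenotypes$disease)) {
    prs <- lapply(c("prs", "microbiome", "prs+microbiome"), function(fs)
      fitAndEvaluate(g, disc$taxa, disc$phenotypes$disease, fs,
                     covariates = pcs, config = prs_cfg))
    names(prs) <- c("prs", "microbiome", "prs+microbiome")
  }
  out <- list(prepared = prep, qc = qc, scans = scans,
              associations = all_assoc, lambda = lambda, thresholds = thr,
              clump_associations = clump_assoc, clump_loci = clump_loci,
              alpha_scan = alpha_scan, beta_scan = beta_scan,
              replication = replication, env = env_scan, prs = prs)
  if (!is.null(outdir)) writePipelineOutputs(out, cohort, outdir)
  out
}

# Replication helper: harmonize the genome-wide set and the suggestive
# pool against the replication scan, assess, and run the enrichment
# test (expected rate from the resampling pool).
replicatePairs <- function(gw, pool, rep_assoc, disc_variants,
                           rep_variants, alpha = 0.05, n_iters = 10,
                           seed = 1L) {
  if (is.null(rep_assoc) || !nrow(rep_assoc)) return(NULL)
  key <- function(df) paste(df$variant, df$trait)
  rep_assoc$chrom2 <- rep_assoc$chrom
  harm_one <- function(set) {
    m <- match(key(set), key(rep_assoc))
    ok <- !is.na(m)
    out <- set[ok, , drop = FALSE]
    r <- rep_assoc[m[ok], , drop = FALSE]
    flip <- out$minor_allele != r$minor_allele
    out$rep_beta <- ifelse(flip, -r$beta, r$beta)
    out$rep_p <- r$p
    out
  }
  hits <- harm_one(gw)
  poolm <- harm_one(pool)
  if (!nrow(hits) || !nrow(poolm)) return(NULL)
  assessed <- assessReplication(hits, alpha)
  report <- tryCatch(
    replicationReport(assessed, poolm, n_iters = n_iters, alpha = alpha,
                      seed = seed),
    error = function(e) NULL)
  list(assessed = assessed, report = report,
       n_unmatched = nrow(gw) - nrow(hits))
}

#' Subset a GenotypeMatrix by variant ids
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param ids variant ids to keep (order preserved as in the panel).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
subsetVariants <- function(genotypes, ids) {
  v <- variantInfo(genotypes)
  keep <- v$id %in% ids
  GenotypeMatrix(dosages(genotypes)[, keep, drop = FALSE],
                 v[keep, c("id", "chrom", "pos", "ref", "alt",
                           "minor_allele")])
}

writePipelineOutputs <- function(out, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  st <- taxonStats(out$prepared)
  w(st, "kept_taxa.tsv")
  writeLines(independentTaxa(out$prepared),
             file.path(outdir, "independent_taxa.txt"))
  w(out$qc, "variant_qc.tsv")
  w(out$associations, "associations_taxa.tsv")
  w(out$alpha_scan, "associations_alpha.tsv")
  w(out$beta_scan, "associations_beta_mds.tsv")
  w(out$clump_associations, "clumped_associations.tsv")
  w(out$clump_loci, "clumped_loci.tsv")
  if (!is.null(out$env)) w(out$env$table, "env_scan.tsv")
  rep_json <- if (!is.null(out$replication) &&
                  !is.null(out$replication$report))
    unclass(out$replication$report) else NULL
  jsonlite::write_json(
    list(lambda = as.list(out$lambda), thresholds = out$thresholds,
         replication = rep_json,
         prs = lapply(out$prs, function(p)
           list(feature_set = p$feature_set, pooled_auc = p$pooled_auc,
                pooled_r2 = p$pooled_r2))),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest <- list(seed = cohort$config$seed,
                   config = unclass(cohort$config),
                   n_independent_taxa = length(independentTaxa(out$prepared)),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
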