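# mgwas

Metagenome-genome-wide association (mgGWAS) analysis in R: does host
genetic variation shape the composition of a host-associated microbial
community, and how does its contribution compare to the environment?

The package is written for microbiome researchers with paired host
genotype (VCF or dosage matrix) and metagenomic taxon-abundance data.
It implements the full analysis arc of a two-cohort mgGWAS study:

* **Taxa as quantitative traits** — occurrence/abundance filtering,
  natural-log transform with 4-SD outlier masking, and greedy selection
  of *independent taxa* from the Spearman correlation graph
  (|ρ| > 0.8 edges): representatives forming an independent dominating
  set whose count sets the study-wide Bonferroni divisor
  (study-wide α = 5×10⁻⁸ / n_independent).
* **Association scans** — per-variant OLS of each taxon trait on
  minor-allele dosage with genotype principal components as covariates
  (β per minor-allele copy, t-based p); logistic scans for binary host
  traits; Shannon α-diversity as a trait; two-axis Bray–Curtis MDS
  scanned with per-variant multivariate models (Pillai's trace);
  genomic-inflation diagnostics (λ_GC = median χ²/0.45494); greedy LD
  clumping (1 Mb, r² ≥ 0.2) into independent associations and loci.
* **Replication** — allele-harmonized same-direction replication
  (p < 0.05), a resampling expectation for the chance replication rate,
  and a continuity-corrected 2×2 χ² enrichment test.
* **Diversity & environment** — genus-level Bray–Curtis, PCoA,
  PERMANOVA, collinearity pruning of environmental covariates
  (Spearman |ρ| > 0.6), per-variable dbRDA with BH-FDR selection, and a
  matched-size comparison of variance explained by top SNPs versus
  significant environmental factors (adjusted R²).
* **Disease prediction** — five-fold cross-validated unweighted
  polygenic risk scores (within-fold selection at p < 10⁻⁵, r² < 0.2
  clumping; PRS = risk-allele count) fed to gradient-boosted trees or
  logistic models, with pooled AUC and R².
* **Synthetic cohorts** — a generator with planted SNP–taxon effects,
  correlated taxon clusters, zero inflation, collinear environment
  covariates and liability-threshold diseases, so the whole pipeline is
  testable without access to controlled cohort data.

## Worked example

Simulate a two-cohort study with 8 planted SNP–taxon effects and a
genetically driven disease, then run the full pipeline:

```r
library(mgwas)

cfg <- simulationConfig(n_discovery = 800, n_replication = 600,
                        n_snps = 1000, n_taxa = 30, n_planted = 8,
                        disease_snp_weight = 0.8, disease_noise_sd = 0.5,
                        seed = 42)
cohort <- simulateCohort(cfg)
run <- runPipeline(cohort, seed = 42)

cat(sprintf("independent taxa: %d -> study-wide threshold %.3g\n",
            length(independentTaxa(run$prepared)),
            run$thresholds$study_wide))
cat(sprintf("lambda_GC across taxa: median %.3f (range %.3f-%.3f)\n",
            median(run$lambda), min(run$lambda), max(run$lambda)))
hits <- subset(run$associations, p < run$thresholds$genome_wide)
truth <- cohort$truth$planted_associations
cat(sprintf("genome-wide associations: %d (%d planted pairs recovered)\n",
            nrow(hits), sum(paste(truth$snp_id, truth$taxon_id) %in%
                            paste(hits$variant, hits$trait))))
print(run$replication$report)
for (p in run$prs) print(p)
```

What it prints (this exact run):

```
independent taxa: 30 -> study-wide threshold 1.67e-09
lambda_GC across taxa: median 1.005 (range 0.886-1.156)
genome-wide associations: 5 (5 planted pairs recovered)
replication: 5/5 (100.00%) vs expected 2.00%; chi2 = 6.086, df = 1, p = 0.0136
prediction [prs]: pooled AUC 0.868, pooled R2 0.312 (5 folds)
prediction [microbiome]: pooled AUC 0.624, pooled R2 -0.029 (5 folds)
prediction [prs+microbiome]: pooled AUC 0.854, pooled R2 0.231 (5 folds)
```

Reading it: all 30 filtered taxa are mutually independent at the
|ρ| > 0.8 threshold, so the study-wide level is 5×10⁻⁸/30 ≈ 1.7×10⁻⁹.
The per-taxon λ_GC median of 1.005 shows a calibrated scan (the spread
is sampling noise at 1000 variants per trait). Five of the eight planted
pairs reach genome-wide significance at n = 800 — the other three fall
below power at this cohort size — and all five replicate in the same
direction in the second cohort, against a ~2% chance expectation
(χ² enrichment p = 0.014). The disease is genetic by construction, so
the PRS model discriminates (AUC 0.87) while the microbiome-only model
adds little.

Individual stages are exported (`prepareTaxa`, `variantQC`,
`linearScan`, `clumpAssociations`, `harmonizeVariants`,
`chi2Enrichment`, `brayCurtis`, `permanova`, `dbrdaEnvScan`,
`fitAndEvaluate`, …) and `writeCohort`/`readVcf`/`readProfile` move
cohorts through VCF and TSV on disk.

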