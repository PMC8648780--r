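---
title: "Methods: metagenome-genome-wide association analysis with mgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metagenome-genome-wide association analysis with mgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`mgwas` implements a metagenome-genome-wide association (mgGWAS)
pipeline: host genetic variants are tested against microbial taxon
abundances treated as quantitative traits, with the surrounding stages a
study of this kind needs — taxon filtering and pruning, inflation
diagnostics, locus clumping, cross-cohort replication with a
resampling-based enrichment test, diversity and environment variance
partitioning, and cross-validated polygenic risk scores for binary
disease outcomes. Real cohorts of this kind are controlled-access, so
the package ships a synthetic-cohort generator with planted effects that
makes every stage testable end to end.

This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, what the generator does and does
not emulate, and the numerical and design choices that were genuinely
open.

# Taxa as quantitative traits

Relative abundances are compositional, zero-inflated and heavy-tailed,
so three preparation steps precede any scan:

1. **Filtering** (`filterTaxa`): a taxon is kept iff its occurrence
   (fraction of samples with non-zero abundance) is at least 90% and its
   mean relative abundance (zeros included) is at least 1e-5. Both
   thresholds are arguments.
2. **Transform** (`transformAbundance`): natural log of the relative
   abundance, after replacing zeros by half the taxon's minimum positive
   abundance (policy `"halfmin"`; `"missing"` masks them instead). Values
   further than 4 SD from the taxon mean are masked missing in a single
   pass — the masking is deliberately not iterated, since re-estimating
   the SD after removal and repeating can cascade on heavy-tailed data.
   The zero policy matters only for taxa near the occurrence boundary:
   under the 90% occurrence filter at most 10% of values are zeros, and
   `halfmin` preserves those samples rather than discarding them.
3. **Independent taxa** (`buildCorrelationGraph`,
   `greedySelectIndependent`): taxa are strongly inter-correlated, so
   the study-wide multiplicity burden is set by a pruned set of
   representatives. Pairwise Spearman correlations (average ranks for
   ties, pairwise-complete samples) define a graph with an edge where
   |rho| > 0.8; the greedy algorithm repeatedly selects the
   highest-degree node (ties at random under a seed, or
   lexicographically for pipelines that must be replayable without a
   seed), removes it and its neighbours, and stops when the graph is
   empty. The output is an independent dominating set: no two selected
   taxa are adjacent and every discarded taxon is correlated with at
   least one representative. The test suite verifies this against brute
   force on hundreds of random graphs.

Two conventions deserve a note. The edge criterion is |rho| > 0.8 on the
*raw* correlation; a `mode = "squared"` variant (rho² above the
threshold) is exposed because both conventions circulate. And the
correlations are computed on raw relative abundances: Spearman is
invariant to the monotone ln transform for complete observations, so the
choice is immaterial there (asserted by a test); it differs only in how
zero-ties interact with the zero policy.

# Association scans

**Variant QC** (`variantQC`) keeps a variant iff MAF ≥ 0.5%, HWE p ≥
1e-5 and call rate ≥ 98%. HWE uses the Pearson chi-square
goodness-of-fit on the three genotype classes (1 df, allele frequency
estimated from the data); the exact test is available via
`hwe_method = "exact"` but the default is the chi-square for speed — on
cohorts simulated under HWE the choice is inconsequential.

**Linear scan** (`linearScan`): per variant, OLS of the trait on
minor-allele dosage plus intercept and covariates (top genotype
principal components by default, `genotypePCs`), over samples complete
for trait, covariates and that variant (complete-case per variant; no
dosage imputation — the simplest defensible contract). The p-value is
two-sided from the t distribution with n − k − 2 df. Internally the
scan residualises trait and dosages against the covariate design once
(Frisch–Waugh), using zero-padded orthonormal projections so the dosage
matrix is never copied per trait; this is algebraically exact and the
tests pin it against `lm()` at 1e-10 relative tolerance. Reported
effects are per copy of the stated minor allele; relabelling alleles
flips the sign exactly.

**Logistic scan** (`logisticScan`): IRLS maximum likelihood per variant,
Wald z and p. Non-convergence and separation (unbounded coefficient)
produce a flagged record with missing beta/se/p rather than a spurious
number.

**Diversity traits**: the Shannon index (`alphaDiversity`) is scanned as
an ordinary quantitative trait. Beta diversity is summarised by the
first two principal-coordinate axes of the genus-level Bray–Curtis
dissimilarity and scanned with a per-variant multivariate linear model
(`betaDiversityScan`); Pillai's trace for the dosage term is computed
directly from the residualised cross-products (exact for a
single-column hypothesis, cross-checked against `stats::manova`), with
the standard F approximation. With one axis it reduces exactly to the
univariate F.

**Calibration and thresholds**: `genomicInflation` reports lambda_GC =
median chi-square / 0.45494; `significanceThresholds` divides the
genome-wide level 5e-8 by the number of independent taxa to give the
study-wide Bonferroni level. **Clumping** (`clumpAssociations`) reduces
records greedily: the most significant remaining record indexes a clump
and absorbs records within 1 Mb (same chromosome, centre to centre)
whose dosage r² with the index is at least 0.2. Clumping within trait
yields "independent associations"; collapsing to the best record per
variant first and clumping across traits yields "independent loci" —
both counts are meaningful and both are emitted.

# Replication and enrichment

`harmonizeVariants` matches discovery and replication records by
position and allele pair and re-signs replication effects to the
discovery minor allele; ambiguous mismatches are dropped with a reason
rather than strand-guessed, which is the right behaviour for synthetic
panels where strand flips cannot occur. An association replicates iff
the replication p is below 0.05 with the same effect direction
(`assessReplication`).

The enrichment question — do the discovery-significant associations
replicate more often than chance? — is answered by drawing, ten times,
as many random associations from the pool of all testable
(variant, trait) pairs as there are discovery hits, averaging their
replication count as the expectation (`resamplingExpectedRate`), and
comparing observed versus expected replicated/non-replicated counts in a
2×2 Pearson chi-square with Yates continuity correction, upper-tail p
(`chi2Enrichment`). Two choices here were open:

* **The pool** is the whole tested universe, not a suggestive-p subset.
  A chance-level expectation (about alpha/2, since direction halves it)
  requires a null-dominated pool; at desk scale a suggestive-only pool
  is dominated by planted true effects and the contrast vanishes.
* **Continuity correction** is included because the corrected statistic
  reproduces the worked 2×2 example this test is anchored to, and
  "one-sided" is read as the usual upper tail of chi-square(1).

With a small discovery set (tens rather than hundreds of hits) the
10-iteration resampling occasionally returns zero replicated events,
leaving the chi-square undefined; the report then substitutes the exact
pool replication rate — the quantity the resampling estimates without
bias — and records `expected_source = "pool"`.

# Diversity and environment

Genus-level Bray–Curtis dissimilarities (`brayCurtis`, via
`vegan::vegdist` after summing lineages), classical-scaling PCoA
(`pcoa`; negative eigenvalues are reported, not corrected, with a
Cailliez option), and PERMANOVA (`permanova`) partitioning the
Gower-centred sums of squares with a row-permutation pseudo-F test. The
PERMANOVA is implemented in the package and cross-checked against
`vegan::adonis2` and against exhaustive enumeration at n = 6 in the
tests.

Environmental variables are pruned for collinearity first
(`pruneCollinearEnv`): any pair with Spearman |rho| > 0.6 loses its
later-listed member, deterministically, until no pair exceeds the limit.
Each surviving variable is tested marginally by distance-based
redundancy analysis (`dbrdaEnvScan`, via `vegan::capscale` and
`anova.cca` permutation tests), with Benjamini–Hochberg control across
variables; the significant set enters a joint model whose explained
variance is reported with the adjusted-R² correction
(`vegan::RsquareAdj`). Marginal (not partial) per-variable tests are the
default, with a `partial` argument, since conditioning changes the
question from "is this variable associated" to "does it add beyond the
others". `geneticsVsEnvVariance` then compares the joint explained
variance of the top k beta-diversity-associated SNPs against that of the
k significant environmental variables — the genetics-versus-environment
comparison at matched model size.

# Polygenic risk scores

`fitAndEvaluate` runs stratified five-fold cross-validation
(`cvSplit`). Within each training fold only: a logistic scan of the
disease (covariate-adjusted by default; the adjustment is a flag because
the convention varies), selection at p < 1e-5, greedy r²-clumping at
0.2 — r² only, no distance window, because the selected set is
genome-sparse (a window flag exists). The PRS is the unweighted count of
risk alleles over the selected SNPs, the risk allele being the one with
positive training-fold log-odds; missing dosages contribute the SNP mean
count. The learner on {PRS}, {taxon abundances} or {PRS + taxa} is
gradient-boosted trees (xgboost: 200 trees, depth 3, learning rate 0.1,
fixed seed — hyperparameters are config fields, not tuned per run) with
a deterministic logistic fallback. Reported metrics: pooled AUC by the
rank statistic (equal to the trapezoidal ROC integral, asserted to
1e-10) and pooled R² of the predicted score against the 0/1 outcome —
the plain coefficient of determination, not Nagelkerke, matching the
"variance explained" reading of R² with a probability-scale predictor.

# The synthetic cohort generator

`simulateCohort` draws one SNP panel and one ground truth, then a
discovery and a replication cohort sharing both. The generator's
defaults are the study conditions under which the package's acceptance
properties are stated, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_discovery`, `n_replication` | 2000, 1000 | cohort sizes |
| `n_snps`, `maf_range` | 5000, (0.05, 0.5) | panel size, MAF range |
| `ld_copy_prob` | 0 | first-order haplotype copying probability |
| `n_subpops`, `fst` | 1, 0 | population structure (Balding–Nichols) |
| `n_taxa` | 50 | taxon panel |
| `n_clusters`, `cluster_size`, `cluster_rho` | 5, 4, 0.6 | correlated taxon clusters |
| `zero_inflation` | 0.05 | detection dropout per taxon |
| `n_planted`, `effect_size_range`, `planted_maf_min` | 20, (0.5, 1.0), 0.1 | causal SNP–taxon pairs |
| `n_env`, `n_collinear_pairs`, `env_effect_size` | 20, 4, 0.3 | environment covariates |
| `disease_prevalence`, `n_disease_snps`, `disease_snp_weight` | 0.2, 10, 0.3 | liability-threshold disease |
| `disease_microbiome_weight`, `disease_noise_sd` | 0.5, 1 | microbiome component, liability noise |

Latent taxon log-abundance is
`z = mu + beta * dosage + gamma * env + cluster factor + noise`;
`exp(z)` is renormalised per sample to sum to one, and zeros are then
injected without re-normalisation, mimicking detection dropout rather
than true absence. Planted betas are defined per copy of the panel ALT
allele so the same physical effect applies in both cohorts regardless of
which allele is minor in-sample. Disease liability is the weighted
dosage sum plus a standardized mean-ln-abundance microbiome score plus
Gaussian noise, thresholded at the empirical prevalence quantile.

Choices worth making explicit:

* **LD by first-order allele copying**, not coalescent simulation: each
  haplotype repeats its previous allele with probability
  `ld_copy_prob`, restarting at chromosome boundaries. This produces the
  adjacent-correlation structure r²-clumping needs; it does not produce
  realistic long-range LD decay, recombination hotspots or allele-age
  structure. At `ld_copy_prob = 1` adjacent SNPs are exact copies, a
  useful degenerate test case.
* **Cluster correlation 0.6 by default**, deliberately below the 0.8
  edge threshold: clustered taxa remain in the independent set, so a
  planted taxon is never silently pruned out of the scan. Raising
  `cluster_rho` above 0.8 exercises the pruning path instead.
* **One master seed, named substreams**: every stage derives its own
  31-bit sub-seed from (seed, stage name), so adding or re-running a
  stage never perturbs the draws of another. Re-runs with the same seed
  are byte-identical apart from manifest timestamps.
* **Effect sizes**: no empirical distribution of real per-allele effects
  on log abundance is available at this scale, so the planted range
  (0.5–1.0 per minor allele, restricted to MAF ≥ 0.1) was fixed at a
  level a well-powered cohort of 2000 detects genome-wide — the regime
  of interest for recovery and false-positive properties. Weaker-effect
  power curves can be explored by changing `effect_size_range`.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: read-level sequencing error
and compositional bias from profiling pipelines; phylogenetic
correlation between taxa (clusters are exchangeable latent factors);
realistic LD and allele-frequency spectra; confounding of environment
with genotype (covariates are drawn independently of ancestry);
non-Gaussian abundance noise beyond the log-normal-with-zeros family;
and case-control ascertainment.

# Numerical choices and problem sizes

Per-variant statistics use closed-form cross-products rather than
repeated model fits; collinear covariates are dropped by QR rank with a
warning; perfect fits floor the p-value at the smallest representable
double rather than reporting zero; tie-breaks in the greedy selection
are seeded; PERMANOVA p-values use the `(exceedances + 1) / (n_perm +
1)` convention. The test-suite and acceptance-script simulations use
cohorts of 500–2000 individuals and 150–5000 SNPs: large enough that the
stated power and calibration properties hold with margin, small enough
to run on one CPU in minutes. One calibration statement is deliberately
about a cohort-level summary: with 2000 variants per trait the per-trait
lambda_GC estimate carries sampling noise of about 0.054 (median-of-
chi-square asymptotics), so the [0.9, 1.1] calibration band is asserted
on the median across the 50 traits, whose noise is an order of magnitude
smaller, not on every individual trait.

# Known limitations

No mixed-model association (GRM-based confounding control) — principal
components are the only structure adjustment, as in the modelled
analysis. No imputation, no X-chromosome dosage conventions, no strand
harmonisation for A/T-C/G variants (dropped with a count instead). The
dbRDA stage tests variables marginally by default. Binary-trait scans
use Wald statistics, which are conservative near separation; separated
fits are flagged, not rescued. The PRS is unweighted by construction —
effect-weighted or shrinkage scores are out of scope.
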