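#' PRS configuration
#'
#' Settings for cross-validated polygenic-risk-score construction:
#' within-fold SNP selection at \code{select_p} with greedy r-squared
#' clumping at \code{select_r2} (no distance window by default, since
#' the selected set is genome-sparse), and the prediction learner.
#'
#' @param n_folds number of cross-validation folds (>= 2).
#' @param select_p per-SNP association p threshold for selection.
#' @param select_r2 clumping r-squared threshold.
#' @param learner "gbdt" (gradient-boosted trees via xgboost) or
#'   "logistic".
#' @param n_trees,max_depth,learning_rate GBDT hyperparameters.
#' @param adjust_covariates include supplied covariates in the
#'   within-fold selection scan.
#' @param seed RNG seed.
#' @return classed list of settings.
#' @export
prsConfig <- function(n_folds = 5, select_p = 1e-5, select_r2 = 0.2,
                      learner = c("gbdt", "logistic"), n_trees = 200,
                      max_depth = 3, learning_rate = 0.1,
                      adjust_covariates = TRUE, seed = 1L) {
  learner <- match.arg(learner)
  stopifnot(n_folds >= 2, select_p > 0, select_p < 1,
            select_r2 >= 0, select_r2 <= 1)
  structure(as.list(environment()), class = "mgwasPrsConfig")
}

#' Stratified cross-validation split
#'
#' Folds are disjoint, cover all samples, and are stratified by case
#' status so per-stratum fold sizes differ by at most one.
#'
#' @param outcome binary 0/1 vector (names = sample ids optional).
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..n_folds) per sample.
#' @export
cvSplit <- function(outcome, n_folds = 5, seed = 1L) {
  stopifnot(length(outcome) >= n_folds)
  if (min(table(outcome)) < n_folds)
    stop("fewer samples in a class than folds; cannot stratify")
  fold <- integer(length(outcome))
  withSubSeed(seed, "cvsplit", {
    for (cls in unique(outcome)) {
      idx <- which(outcome == cls)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  fold
}

#' Select PRS SNPs within a training fold
#'
#' Logistic association scan of the disease on each SNP within the
#' training samples only, selection at \code{select_p}, then greedy
#' r-squared clumping of the selected set (most significant first). The
#' risk allele of each selected SNP is the allele with positive
#' log-odds: the minor allele if beta > 0, the major allele otherwise.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} (training samples only;
#'   test samples must not appear).
#' @param outcome binary vector for the training samples.
#' @param covariates optional covariates for the selection scan.
#' @param config a \code{\link{prsConfig}}.
#' @return data.frame: variant, beta, p, risk_allele, risk_is_minor; zero
#'   rows when nothing reaches \code{select_p}.
#' @export
selectPrsSnps <- function(genotypes, outcome, covariates = NULL,
                          config = prsConfig()) {
  if (!config$adjust_covariates) covariates <- NULL
  scan <- logisticScan(genotypes, outcome, covariates,
                       trait_id = "disease")
  sel <- scan[!is.na(scan$p) & scan$p < config$select_p & scan$converged, ,
              drop = FALSE]
  if (!nrow(sel))
    return(data.frame(variant = character(), beta = numeric(),
                      p = numeric(), risk_allele = character(),
                      risk_is_minor = logical()))
  sel <- sel[order(sel$p), , drop = FALSE]
  d <- dosages(genotypes)
  keep <- integer()
  for (i in seq_len(nrow(sel))) {
    ok <- TRUE
    for (j in keep) {
      x <- d[, sel$variant[i]]; yv <- d[, sel$variant[j]]
      use <- !is.na(x) & !is.na(yv)
      if (sum(use) >= 3 && sd(x[use]) > 0 && sd(yv[use]) > 0 &&
          cor(x[use], yv[use])^2 >= config$select_r2) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  sel <- sel[keep, , drop = FALSE]
  v <- variantInfo(genotypes)
  m <- v[match(sel$variant, v$id), ]
  major <- ifelse(m$minor_allele == m$alt, m$ref, m$alt)
  data.frame(variant = sel$variant, beta = sel$beta, p = sel$p,
             risk_allele = ifelse(sel$beta > 0, m$minor_allele, major),
             risk_is_minor = sel$beta > 0, row.names = NULL)
}

#' Unweighted polygenic risk score
#'
#' PRS = sum over selected SNPs of the per-sample count of risk alleles
#' (0/1/2). Missing dosages contribute the SNP's mean risk-allele count
#' (logged via message). An empty selection yields an all-zero score.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} for the samples to
#'   score.
#' @param risk_snps data.frame from \code{\link{selectPrsSnps}}.
#' @return named numeric vector of scores.
#' @export
computePrs <- function(genotypes, risk_snps) {
  d <- dosages(genotypes)
  prs <- setNames(rep(0, nrow(d)), rownames(d))
  if (!nrow(risk_snps)) {
    attr(prs, "empty_selection") <- TRUE
    return(prs)
  }
  stopifnot(all(risk_snps$variant %in% colnames(d)))
  v <- variantInfo(genotypes)
  for (i in seq_len(nrow(risk_snps))) {
    x <- d[, risk_snps$variant[i]]
    j <- match(risk_snps$variant[i], v$id)
    # risk allele may be this cohort's major allele: complement the count
    cnt <- if (risk_snps$risk_allele[i] == v$minor_allele[j]) x else 2 - x
    if (anyNA(cnt)) {
      message("mean-imputing ", sum(is.na(cnt)), " missing dosage(s) for ",
              risk_snps$variant[i])
      cnt[is.na(cnt)] <- mean(cnt, na.rm = TRUE)
    }
    prs <- prs + cnt
  }
  prs
}

trainPredict <- function(xtr, ytr, xte, config) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  if (config$learner == "gbdt") {
    booster <- xgboost::xgboost(
      x = xtr, y = factor(ytr, levels = 0:1),
      objective = "binary:logistic", nrounds = config$n_trees,
      max_depth = config$max_depth, learning_rate = config$learning_rate,
      nthreads = 1, seed = subSeed(config$seed, "xgb"), verbosity = 0)
    predict(booster, xte, type = "response")
  } else {
    df <- as.data.frame(xtr)
    fit <- suppressWarnings(glm(ytr ~ ., data = df,
                                family = binomial()))
    as.numeric(predict(fit, newdata = as.data.frame(xte),
                       type = "response"))
  }
}

#' Cross-validated disease prediction from PRS and microbiome features
#'
#' For each fold: selects PRS SNPs on the training samples only, scores
#' training and held-out samples, trains the learner on the requested
#' feature set ({PRS}, {taxon relative abundances}, or {PRS + taxa}),
#' and predicts the held-out fold. Pooled R2 is the coefficient of
#' determination of the predicted score against the 0/1 outcome; pooled
#' AUC is the rank-statistic AUC.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} for all samples.
#' @param taxa \linkS4class{TaxaProfile} (used for microbiome feature
#'   sets; may be NULL for "prs").
#' @param outcome binary 0/1 vector.
#' @param feature_set "prs", "microbiome" or "prs+microbiome".
#' @param covariates optional covariates for the selection scan.
#' @param config a \code{\link{prsConfig}}.
#' @return list of class \code{mgwasPredictionReport}: feature_set,
#'   folds (per-fold AUC/R2/n_snps), pooled_auc, pooled_r2,
#'   predictions.
#' @export
fitAndEvaluate <- function(genotypes, taxa, outcome,
                           feature_set = c("prs", "microbiome",
                                           "prs+microbiome"),
                           covariates = NULL, config = prsConfig()) {
  feature_set <- match.arg(feature_set)
  d <- dosages(genotypes)
  outcome <- alignVector(outcome, rownames(d))
  fold <- cvSplit(outcome, config$n_folds, config$seed)
  pred <- rep(NA_real_, length(outcome))
  folds <- data.frame(fold = seq_len(config$n_folds), auc = NA_real_,
                      r2 = NA_real_, n_snps = NA_integer_)
  amat <- if (!is.null(taxa)) abundances(taxa) else NULL
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f; te <- !tr
    feats_tr <- NULL; feats_te <- NULL
    nsnp <- 0L
    if (feature_set %in% c("prs", "prs+microbiome")) {
      gtr <- subsetSamples(genotypes, which(tr))
      risk <- selectPrsSnps(gtr, outcome[tr],
                            if (!is.null(covariates))
                              as.matrix(covariates)[tr, , drop = FALSE],
                            config)
      nsnp <- nrow(risk)
      prs_all <- computePrs(genotypes, risk)
      feats_tr <- cbind(feats_tr, prs = prs_all[tr])
      feats_te <- cbind(feats_te, prs = prs_all[te])
    }
    if (feature_set %in% c("microbiome", "prs+microbiome")) {
      feats_tr <- cbind(feats_tr, amat[tr, , drop = FALSE])
      feats_te <- cbind(feats_te, amat[te, , drop = FALSE])
    }
    pf <- trainPredict(feats_tr, outcome[tr], feats_te, config)
    pred[te] <- pf
    folds$auc[f] <- rankAuc(pf, outcome[te])
    folds$r2[f] <- 1 - sum((outcome[te] - pf)^2) /
      sum((outcome[te] - mean(outcome[te]))^2)
    folds$n_snps[f] <- nsnp
  }
  structure(list(feature_set = feature_set, folds = folds,
                 pooled_auc = rankAuc(pred, outcome),
                 pooled_r2 = 1 - sum((outcome - pred)^2) /
                   sum((outcome - mean(outcome))^2),
                 predictions = data.frame(sample = rownames(d),
                                          fold = fold, outcome = outcome,
                                          predicted = pred)),
            class = "mgwasPredictionReport")
}

#' @export
print.mgwasPredictionReport <- function(x, ...) {
  cat(sprintf("prediction [%s]: pooled AUC %.3f, pooled R2 %.3f (%d folds)\n",
              x$feature_set, x$pooled_auc, x$pooled_r2, nrow(x$folds)))
  invisible(x)
}

#' Subset a GenotypeMatrix by samples
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param idx row indices or sample ids.
#' @return a new \linkS4class{GenotypeMatrix} with QC statistics
#'   recomputed on the subset (minor allele re-polarised in-sample).
#' @export
subsetSamples <- function(genotypes, idx) {
  d <- dosages(genotypes)[idx, , drop = FALSE]
  v <- variantInfo(genotypes)
  GenotypeMatrix(d, v[, c("id", "chrom", "pos", "ref", "alt",
                          "minor_allele")])
}
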