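#' Scan configuration
#'
#' Thresholds for variant QC, significance and clumping. Defaults: keep
#' common and low-frequency variants (MAF >= 0.5 percent), HWE p >=
#' 1e-5, call rate >= 98 percent; genome-wide alpha 5e-8; four genotype
#' principal components as covariates; clumping at 1 Mb / r2 0.2.
#'
#' @param maf_min,hwe_min,callrate_min variant QC thresholds.
#' @param gw_alpha genome-wide significance level.
#' @param n_pcs number of genotype principal components to include.
#' @param covariate_ids names of covariate columns to include in scans.
#' @param clump_window_bp,clump_r2 clumping window (bp, centre to
#'   centre) and dosage-correlation r-squared threshold.
#' @param hwe_method "chisq" (Pearson goodness of fit, 1 df) or "exact".
#' @return classed list of settings.
#' @export
scanConfig <- function(maf_min = 0.005, hwe_min = 1e-5,
                       callrate_min = 0.98, gw_alpha = 5e-8, n_pcs = 4,
                       covariate_ids = character(),
                       clump_window_bp = 1e6, clump_r2 = 0.2,
                       hwe_method = "chisq") {
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_min >= 0, hwe_min <= 1,
            callrate_min >= 0, callrate_min <= 1, gw_alpha > 0,
            gw_alpha < 1, n_pcs >= 0, clump_window_bp >= 0,
            clump_r2 >= 0, clump_r2 <= 1)
  structure(as.list(environment()), class = "mgwasScanConfig")
}

#' Variant quality control
#'
#' Keeps a variant iff MAF >= \code{maf_min}, HWE p >= \code{hwe_min}
#' and call rate >= \code{callrate_min}. HWE defaults to the Pearson
#' chi-square goodness-of-fit on genotype counts (1 df); an exact test
#' is available via the config. Monomorphic variants fail with reason
#' "maf".
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param config a \code{\link{scanConfig}}.
#' @return data.frame: id, maf, hwe_p, call_rate, pass, reason.
#' @export
variantQC <- function(genotypes, config = scanConfig()) {
  v <- variantInfo(genotypes)
  d <- dosages(genotypes)
  hwe <- if (config$hwe_method == "exact")
    apply(d, 2, function(x) hweExactTest(x)$p) else v$hwe_p
  reason <- character(nrow(v))
  reason[v$call_rate < config$callrate_min] <- "call_rate"
  reason[!is.na(hwe) & hwe < config$hwe_min] <- "hwe"
  reason[v$maf < config$maf_min] <- "maf"
  data.frame(id = v$id, maf = v$maf, hwe_p = hwe,
             call_rate = v$call_rate, pass = reason == "",
             reason = reason, row.names = NULL)
}

#' Leading genotype principal components
#'
#' Principal components of the centred dosage matrix (missing dosages
#' mean-imputed for the decomposition only), the standard population
#' structure covariates.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param n_pcs number of components.
#' @return samples x n_pcs matrix with columns PC1..PCn.
#' @export
genotypePCs <- function(genotypes, n_pcs = 4) {
  d <- dosages(genotypes)
  cm <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- cm[j]
  d <- sweep(d, 2, colMeans(d))
  keep <- colSums(d^2) > 0
  d <- d[, keep, drop = FALSE]
  # eigendecompose the smaller Gram matrix: scores are identical to the
  # singular vectors scaled by their singular values
  if (nrow(d) <= ncol(d)) {
    e <- eigen(tcrossprod(d), symmetric = TRUE)
    pcs <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(n_pcs)], 0)), n_pcs)
  } else {
    e <- eigen(crossprod(d), symmetric = TRUE)
    pcs <- d %*% e$vectors[, seq_len(n_pcs), drop = FALSE]
  }
  dimnames(pcs) <- list(rownames(d), paste0("PC", seq_len(n_pcs)))
  pcs
}

# Validate and assemble the covariate design (intercept + covariates),
# dropping aliased columns with a warning.
buildDesign <- function(covariates, rows) {
  if (is.null(covariates)) return(matrix(1, length(rows), 1))
  cv <- as.matrix(covariates)[rows, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, cv)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    warning("dropping collinear covariate(s): ", paste(drop, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  X
}

# Project y (vector or matrix) onto the orthogonal complement of X,
# via an explicit orthonormal basis so wide matrices go through BLAS.
residualize <- function(y, X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  y - Q %*% crossprod(Q, y)
}

emptyScanResult <- function() {
  data.frame(variant = character(), chrom = character(), pos = integer(),
             minor_allele = character(), maf = numeric(), trait = character(),
             n = integer(), beta = numeric(), se = numeric(),
             stat = numeric(), p = numeric(), model = character())
}

#' Per-variant linear association scan
#'
#' Ordinary least squares of a quantitative trait on minor-allele dosage
#' plus intercept and covariates, per variant, over samples complete for
#' trait, covariates and that variant's dosage (complete-case; no
#' imputation). Reports the per-minor-allele-copy effect, its standard
#' error, the t statistic and the two-sided p from the t distribution
#' with n - k - 2 degrees of freedom (k covariates).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param trait named or sample-aligned numeric vector.
#' @param covariates optional samples x k matrix/data.frame aligned with
#'   the genotypes.
#' @param config a \code{\link{scanConfig}} (not used for QC here; run
#'   \code{\link{variantQC}} upstream and subset).
#' @param trait_id label for the output.
#' @return data.frame of association records (one per variant).
#' @export
linearScan <- function(genotypes, trait, covariates = NULL,
                       config = scanConfig(), trait_id = "trait") {
  d <- dosages(genotypes)
  v <- variantInfo(genotypes)
  trait <- alignVector(trait, rownames(d))
  ok <- !is.na(trait)
  if (!is.null(covariates))
    ok <- ok & complete.cases(as.matrix(covariates))
  if (sd(trait[ok]) == 0 || sum(ok) < 3) {
    warning("trait '", trait_id, "' constant or too few samples; skipped")
    return(emptyScanResult())
  }
  X <- buildDesign(covariates, which(ok))
  k <- ncol(X) - 1
  y <- trait[ok]
  ry <- residualize(y, X)
  nall <- nrow(d)
  drop_rows <- which(!ok)
  nmiss <- if (anyNA(d)) {
    nm <- colSums(is.na(d))
    if (length(drop_rows))
      nm <- nm - colSums(is.na(d[drop_rows, , drop = FALSE]))
    nm
  } else rep(0L, ncol(d))
  res <- matrix(NA_real_, ncol(d), 5,
                dimnames = list(colnames(d), c("n", "beta", "se", "stat", "p")))
  full <- which(nmiss == 0)
  if (length(full)) {
    # Work on the full matrix with zero-padded projections instead of
    # copying row subsets: with Q an orthonormal basis of the design on
    # the used rows (padded with zeros elsewhere), |x~|^2 = |x|^2 -
    # |Q'x|^2 over those rows, and ry (also zero-padded) is orthogonal
    # to the design, so crossprod(d, ry) gives x~'y~ directly.
    qX <- qr(X)
    Q <- qr.Q(qX)[, seq_len(qX$rank), drop = FALSE]
    Zq <- matrix(0, nall, ncol(Q))
    Zq[ok, ] <- Q
    zy <- numeric(nall)
    zy[ok] <- ry
    d0 <- d
    if (anyNA(d0)) d0[is.na(d0)] <- 0   # full columns are unaffected
    css <- colSums(d0 * d0)
    if (length(drop_rows))
      css <- css - colSums(d0[drop_rows, , drop = FALSE]^2)
    C <- crossprod(Zq, d0)
    sxx <- pmax(css - colSums(C^2), 0)[full]
    sxy <- as.vector(crossprod(d0, zy))[full]
    beta <- ifelse(sxx > 1e-12, sxy / sxx, NA)
    df <- length(y) - k - 2
    rss <- pmax(sum(ry^2) - beta^2 * sxx, 0)
    se <- sqrt(rss / df / sxx)
    tt <- beta / se
    p <- 2 * pt(-abs(tt), df)
    res[full, ] <- cbind(length(y), beta, se, tt, p)
  }
  for (j in which(nmiss > 0)) {
    xj <- d[ok, j]
    use <- !is.na(xj)
    if (sum(use) < k + 3) next
    Xj <- X[use, , drop = FALSE]
    ryj <- residualize(y[use], Xj)
    rdj <- residualize(xj[use], Xj)
    sxx <- sum(rdj^2)
    if (sxx <= 1e-12) next
    beta <- sum(rdj * ryj) / sxx
    df <- sum(use) - k - 2
    rss <- max(sum(ryj^2) - beta^2 * sxx, 0)
    se <- sqrt(rss / df / sxx)
    res[j, ] <- c(sum(use), beta, se, beta / se,
                  2 * pt(-abs(beta / se), df))
  }
  out <- data.frame(variant = v$id, chrom = v$chrom, pos = v$pos,
                    minor_allele = v$minor_allele, maf = v$maf,
                    trait = trait_id, n = res[, "n"], beta = res[, "beta"],
                    se = res[, "se"], stat = res[, "stat"], p = res[, "p"],
                    model = "linear", row.names = NULL)
  out$p <- pmax(out$p, .Machine$double.xmin)
  out
}

alignVector <- function(x, ids) {
  if (!is.null(names(x))) {
    stopifnot(all(ids %in% names(x)))
    x <- x[ids]
  } else stopifnot(length(x) == length(ids))
  as.numeric(x)
}

#' Per-variant logistic association scan
#'
#' Maximum-likelihood logistic regression (IRLS via \code{glm.fit}) of a
#' binary outcome on dosage plus intercept and covariates; Wald z and p
#' per variant. Non-convergence or separation (divergent coefficient) is
#' flagged: the record is kept with missing beta/se/p.
#'
#' @inheritParams linearScan
#' @param outcome binary 0/1 vector.
#' @return data.frame of association records with a \code{converged}
#'   column.
#' @export
logisticScan <- function(genotypes, outcome, covariates = NULL,
                         config = scanConfig(), trait_id = "outcome") {
  d <- dosages(genotypes)
  v <- variantInfo(genotypes)
  outcome <- alignVector(outcome, rownames(d))
  ok <- !is.na(outcome)
  if (!is.null(covariates))
    ok <- ok & complete.cases(as.matrix(covariates))
  tab <- table(factor(outcome[ok], levels = 0:1))
  if (any(tab == 0)) {
    warning("outcome '", trait_id, "' has a single class; skipped")
    return(cbind(emptyScanResult(), converged = logical()))
  }
  if (any(tab < 10))
    warning("outcome '", trait_id, "' has a class with fewer than 10 samples")
  X <- buildDesign(covariates, which(ok))
  y <- outcome[ok]
  D <- d[ok, , drop = FALSE]
  fit1 <- function(x) {
    use <- !is.na(x)
    M <- cbind(X[use, , drop = FALSE], dosage = x[use])
    f <- tryCatch(suppressWarnings(
      glm.fit(M, y[use], family = binomial())), error = function(e) NULL)
    if (is.null(f) || !f$converged)
      return(c(sum(use), NA, NA, NA, NA, 0))
    b <- coef(f)["dosage"]
    # Wald se from the Fisher information at the fit
    w <- f$weights
    XtWX <- crossprod(M * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) return(c(sum(use), NA, NA, NA, NA, 0))
    se <- sqrt(diag(cov))[ncol(M)]
    if (!is.finite(b) || abs(b) > 15 || !is.finite(se) || se > 100)
      return(c(sum(use), NA, NA, NA, NA, 0))  # separation flag
    z <- b / se
    c(sum(use), b, se, z, 2 * pnorm(-abs(z)), 1)
  }
  res <- t(apply(D, 2, fit1))
  out <- data.frame(variant = v$id, chrom = v$chrom, pos = v$pos,
                    minor_allele = v$minor_allele, maf = v$maf,
                    trait = trait_id, n = res[, 1], beta = res[, 2],
                    se = res[, 3], stat = res[, 4], p = res[, 5],
                    model = "logistic", converged = res[, 6] == 1,
                    row.names = NULL)
  out$p <- pmax(out$p, .Machine$double.xmin)
  out$p[is.na(res[, 5])] <- NA
  out
}

#' Shannon alpha diversity per sample
#'
#' \code{H = -sum(q log q)} over taxa with positive abundance, where q
#' is the sample's abundance renormalised to sum to one. All-zero
#' samples get NA.
#'
#' @param profile a \linkS4class{TaxaProfile}.
#' @return named numeric vector of Shannon indices (natural log).
#' @export
alphaDiversity <- function(profile) {
  a <- abundances(profile)
  apply(a, 1, function(x) {
    s <- sum(x, na.rm = TRUE)
    if (is.na(s) || s <= 0) return(NA_real_)
    q <- x[!is.na(x) & x > 0] / s
    -sum(q * log(q))
  })
}

#' Multivariate association scan for beta-diversity ordination axes
#'
#' Per variant, a multivariate linear model of the MDS axes on dosage
#' plus covariates; Pillai's trace for the dosage term with its standard
#' F approximation. With a single axis the Pillai F reduces exactly to
#' the univariate regression F.
#'
#' @inheritParams linearScan
#' @param axes samples x a matrix of ordination axes (two for the usual
#'   two-axis MDS).
#' @return data.frame of association records; \code{beta} is the effect
#'   on the first axis, \code{stat} is Pillai's trace.
#' @export
betaDiversityScan <- function(genotypes, axes, covariates = NULL,
                              config = scanConfig(), trait_id = "beta_mds") {
  d <- dosages(genotypes)
  v <- variantInfo(genotypes)
  axes <- as.matrix(axes)
  stopifnot(nrow(axes) == nrow(d))
  ok <- complete.cases(axes)
  if (!is.null(covariates))
    ok <- ok & complete.cases(as.matrix(covariates))
  X <- buildDesign(covariates, which(ok))
  k <- ncol(X) - 1
  Y <- axes[ok, , drop = FALSE]
  D <- d[ok, , drop = FALSE]
  p_resp <- ncol(Y)
  q0 <- qr(X)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  RY <- Y - Q0 %*% crossprod(Q0, Y)
  fitj <- function(x) {
    use <- !is.na(x)
    if (all(use)) {
      ry <- RY
      rx <- x - Q0 %*% crossprod(Q0, x)
    } else {
      xq <- X[use, , drop = FALSE]
      ry <- residualize(Y[use, , drop = FALSE], xq)
      rx <- residualize(x[use], xq)
    }
    sxx <- sum(rx^2)
    n <- sum(use)
    if (sxx <= 1e-12) return(c(n, NA, NA, NA))
    h <- crossprod(ry, rx) / sqrt(sxx)      # p_resp x 1
    H <- tcrossprod(h)
    E <- crossprod(ry) - H
    V <- sum(diag(H %*% solve(H + E)))
    ve <- n - k - 2
    Fst <- (V / (1 - V)) * (ve - p_resp + 1) / p_resp
    pv <- pf(Fst, p_resp, ve - p_resp + 1, lower.tail = FALSE)
    c(n, V, Fst, pv, h[1] / sqrt(sxx))
  }
  res <- t(apply(D, 2, function(x) {
    r <- fitj(x); length(r) <- 5; r
  }))
  out <- data.frame(variant = v$id, chrom = v$chrom, pos = v$pos,
                    minor_allele = v$minor_allele, maf = v$maf,
                    trait = trait_id, n = res[, 1], beta = res[, 5],
                    se = NA_real_, stat = res[, 2], p = res[, 4],
                    model = "manova_pillai", row.names = NULL)
  out$p <- pmax(out$p, .Machine$double.xmin)
  out$p[is.na(res[, 4])] <- NA
  out
}

#' Genomic inflation factor
#'
#' \code{lambda_GC} = median of the per-variant 1-df chi-square
#' statistics divided by the chi-square(1) median (0.45494). P-values
#' are converted through the inverse upper tail. Near 1 indicates a
#' well-calibrated scan.
#'
#' @param p vector of p-values (or NULL).
#' @param stat vector of 1-df chi-square statistics (used if p is NULL).
#' @return lambda (numeric scalar).
#' @export
genomicInflation <- function(p = NULL, stat = NULL) {
  if (is.null(stat)) {
    if (is.null(p) || !length(p)) stop("need p-values or statistics")
    stat <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (!length(stat)) stop("empty input")
  if (length(stat) < 100)
    warning("fewer than 100 tests; lambda estimate is noisy")
  median(stat, na.rm = TRUE) / qchisq(0.5, df = 1)
}

#' Genome-wide and study-wide significance thresholds
#'
#' The study-wide threshold Bonferroni-divides the genome-wide level by
#' the number of independent traits scanned (e.g. 5e-8 / 1583 =
#' 3.16e-11).
#'
#' @param gw_alpha genome-wide level.
#' @param n_independent_traits Bonferroni divisor (>= 1).
#' @return list(genome_wide, study_wide).
#' @export
significanceThresholds <- function(gw_alpha = 5e-8, n_independent_traits) {
  stopifnot(n_independent_traits >= 1)
  list(genome_wide = gw_alpha,
       study_wide = gw_alpha / n_independent_traits)
}

#' Greedy LD clumping of association records
#'
#' Repeatedly takes the most significant remaining record as an index
#' and absorbs records whose variant lies within
#' \code{clump_window_bp} (same chromosome, centre to centre) of the
#' index and whose dosage correlation r-squared with it is at least
#' \code{clump_r2}. With scope \code{"per_trait"} clumping is done
#' within each trait ("independent associations"); with scope
#' \code{"variants"} records are first collapsed to the best p per
#' variant and clumped across traits ("independent loci").
#'
#' @param results association data.frame from a scan.
#' @param genotypes a \linkS4class{GenotypeMatrix} covering the result
#'   variants (for r-squared).
#' @param config a \code{\link{scanConfig}}.
#' @param scope "per_trait" or "variants".
#' @return input records (collapsed for scope "variants") with added
#'   columns \code{index} (id of the clump's index variant) and
#'   \code{is_index}.
#' @export
clumpAssociations <- function(results, genotypes, config = scanConfig(),
                              scope = c("per_trait", "variants")) {
  scope <- match.arg(scope)
  if (!nrow(results)) return(cbind(results, index = character(),
                                   is_index = logical()))
  d <- dosages(genotypes)
  if (scope == "variants") {
    o <- order(results$p)
    results <- results[o, ][!duplicated(results$variant[o]), , drop = FALSE]
    results$trait <- "(any)"
  }
  r2 <- function(a, b) {
    x <- d[, a]; y <- d[, b]
    use <- !is.na(x) & !is.na(y)
    if (sum(use) < 3 || sd(x[use]) == 0 || sd(y[use]) == 0) {
      warning("missing/degenerate genotypes for r2: ", a, " vs ", b,
              "; treated as 0")
      return(0)
    }
    cor(x[use], y[use])^2
  }
  clumpOne <- function(df) {
    df <- df[order(df$p), , drop = FALSE]
    df$index <- NA_character_
    remaining <- seq_len(nrow(df))
    while (length(remaining)) {
      i <- remaining[1]
      df$index[i] <- df$variant[i]
      rest <- remaining[-1]
      if (length(rest)) {
        near <- df$chrom[rest] == df$chrom[i] &
          abs(df$pos[rest] - df$pos[i]) < config$clump_window_bp
        absorb <- rest[near][vapply(df$variant[rest[near]],
                                    function(v) r2(v, df$variant[i]) >=
                                      config$clump_r2, logical(1))]
        df$index[absorb] <- df$variant[i]
        remaining <- setdiff(rest, absorb)
      } else remaining <- integer()
    }
    df
  }
  out <- do.call(rbind, lapply(split(results, results$trait), clumpOne))
  rownames(out) <- NULL
  out$is_index <- out$variant == out$index
  out
}
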