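#' Genus-level Bray-Curtis dissimilarity
#'
#' Aggregates abundances to the requested taxonomic level by summing
#' within lineage (using the profile's taxonomy strings), then computes
#' Bray-Curtis dissimilarity \code{d(x, y) = sum|x - y| / sum(x + y)}
#' via \code{vegan::vegdist}. Samples with zero total abundance are
#' excluded with a warning.
#'
#' @param profile a \linkS4class{TaxaProfile}.
#' @param level "genus" (aggregate on the g__ lineage field) or "taxon"
#'   (no aggregation).
#' @return a \code{dist} object of Bray-Curtis dissimilarities.
#' @export
brayCurtis <- function(profile, level = c("genus", "taxon")) {
  level <- match.arg(level)
  a <- abundances(profile)
  if (level == "genus" && length(taxonomy(profile))) {
    lin <- taxonomy(profile)[colnames(a)]
    genus <- sub(".*(g__[^|]+).*", "\\1", lin)
    genus[is.na(genus)] <- colnames(a)[is.na(genus)]
    a <- t(rowsum(t(a), genus))
  }
  tot <- rowSums(a, na.rm = TRUE)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " sample(s) with zero total abundance excluded")
    a <- a[tot > 0, , drop = FALSE]
  }
  vegan::vegdist(a, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical scaling (Gower double-centring + eigendecomposition) of a
#' distance matrix; returns the top positive-eigenvalue axes scaled by
#' the square root of their eigenvalues. Negative eigenvalues are
#' reported, not corrected, unless Cailliez correction is requested.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @param n_axes number of axes to return.
#' @param correction "none" or "cailliez".
#' @return list: \code{axes} (samples x n_axes, columns MDS1..),
#'   \code{eigenvalues} (all), \code{negative} (count of negative
#'   eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.dist(d)
  n <- attr(d, "Size")
  # k = n - 1 requested deliberately; cmdscale warns when some of those
  # axes have non-positive eigenvalues, which is expected for semimetrics
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE,
                                   add = correction == "cailliez"))
  eig <- fit$eig
  npos <- sum(eig > 1e-8)
  if (npos == 0) stop("no positive eigenvalues; degenerate distances")
  k <- min(n_axes, npos)
  axes <- fit$points[, seq_len(k), drop = FALSE]
  colnames(axes) <- paste0("MDS", seq_len(k))
  list(axes = axes, eigenvalues = eig, negative = sum(eig < -1e-8))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities between the
#' model and residual using the Gower-centred inner-product matrix and
#' the hat matrix of the (intercept-augmented) model; the pseudo-F is
#' tested by permuting sample rows. \code{p = (#permuted F >= observed
#' + 1) / (n_perm + 1)}.
#'
#' @param d a \code{dist} or symmetric dissimilarity matrix.
#' @param rhs grouping factor, numeric vector, or model data.frame.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list: pseudo_F, R2, p, df.
#' @export
permanova <- function(d, rhs, n_perm = 999, seed = 1L) {
  D <- as.matrix(as.dist(d))
  n <- nrow(D)
  stopifnot(n >= 5)
  X <- if (is.data.frame(rhs)) stats::model.matrix(~ ., rhs)
       else stats::model.matrix(~ rhs)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < 2) stop("model has no non-constant term (single group?)")
  # Gower-centred inner products
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  m <- qr(X)$rank - 1
  fstat <- function(perm) {
    Xp <- X[perm, , drop = FALSE]
    q <- qr(Xp)
    H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    ssm <- sum(H * G) - sum(G) / n
    sst <- sum(diag(G))
    ssr <- sst - ssm
    (ssm / m) / (ssr / (n - m - 1))
  }
  Fobs <- fstat(seq_len(n))
  perms <- withSubSeed(seed, "permanova",
                       replicate(n_perm, fstat(sample.int(n))))
  H <- tcrossprod(qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE])
  ssm <- sum(H * G)          # intercept direction contributes 0 (G centred)
  sst <- sum(diag(G))
  list(pseudo_F = Fobs, R2 = ssm / sst,
       p = (sum(perms >= Fobs) + 1) / (n_perm + 1),
       df = c(model = m, residual = n - m - 1))
}

#' Compare alpha diversity between two profiles
#'
#' Shannon index per sample in each group, two-sided Wilcoxon rank-sum
#' test with tie correction.
#'
#' @param profile_a,profile_b \linkS4class{TaxaProfile}s for the two
#'   groups.
#' @return list: mean_a, mean_b, p, statistic.
#' @export
alphaCompare <- function(profile_a, profile_b) {
  ha <- alphaDiversity(profile_a)
  hb <- alphaDiversity(profile_b)
  if (sum(!is.na(ha)) < 3 || sum(!is.na(hb)) < 3)
    warning("fewer than 3 samples in a group; p-value unstable")
  w <- suppressWarnings(wilcox.test(ha, hb, exact = FALSE))
  list(mean_a = mean(ha, na.rm = TRUE), mean_b = mean(hb, na.rm = TRUE),
       p = w$p.value, statistic = unname(w$statistic))
}

#' Prune collinear environmental variables
#'
#' Computes pairwise Spearman correlations and iterates over collinear
#' pairs (|rho| > \code{rho_limit}), dropping the later-listed member of
#' each pair, until no pair exceeds the limit. Constant variables are
#' dropped with a reason.
#'
#' @param env data.frame of numeric/binary variables (log-transform
#'   quantitative variables upstream).
#' @param rho_limit collinearity threshold (default 0.6).
#' @return list: \code{kept} variable names, \code{dropped} data.frame
#'   (variable, reason/partner).
#' @export
pruneCollinearEnv <- function(env, rho_limit = 0.6) {
  env <- as.data.frame(env)
  dropped <- data.frame(variable = character(), reason = character())
  if (!ncol(env)) return(list(kept = character(), dropped = dropped))
  const <- vapply(env, function(x) sd(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)), logical(1))
  if (any(const)) {
    dropped <- rbind(dropped, data.frame(variable = names(env)[const],
                                         reason = "constant"))
    env <- env[, !const, drop = FALSE]
  }
  keep <- names(env)
  rho <- suppressWarnings(cor(as.matrix(env), method = "spearman",
                              use = "pairwise.complete.obs"))
  repeat {
    r <- rho[keep, keep, drop = FALSE]
    diag(r) <- 0
    hit <- which(abs(r) > rho_limit, arr.ind = TRUE)
    if (!nrow(hit)) break
    # first-listed member of the first offending pair is retained
    pair <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    drop <- keep[max(pair)]
    dropped <- rbind(dropped,
                     data.frame(variable = drop,
                                reason = paste0("collinear_with:",
                                                keep[min(pair)])))
    keep <- setdiff(keep, drop)
    if (length(keep) < 2) break
  }
  list(kept = keep, dropped = dropped)
}

#' Distance-based redundancy analysis scan of environmental variables
#'
#' Per variable, a marginal dbRDA (\code{vegan::capscale}) of the
#' dissimilarity matrix on that variable: R2 = constrained inertia /
#' total inertia, permutation pseudo-F p (\code{vegan::anova.cca}),
#' then Benjamini-Hochberg adjustment across variables. Variables
#' significant at the FDR are combined in a joint model whose explained
#' variance is reported with the adjusted-R2 correction
#' (\code{vegan::RsquareAdj}).
#'
#' @param d a \code{dist} of community dissimilarities.
#' @param env data.frame of candidate variables (rows aligned with d).
#' @param n_perm permutations for each per-variable test.
#' @param fdr BH threshold for inclusion in the joint model.
#' @param seed RNG seed.
#' @param partial optional data.frame of conditioning variables
#'   (partial dbRDA); NULL for marginal tests.
#' @return list: \code{table} (variable, F, R2, p, q, significant),
#'   \code{joint} (R2, adj_R2, variables) or NULL if none significant.
#' @export
dbrdaEnvScan <- function(d, env, n_perm = 999, fdr = 0.05, seed = 1L,
                         partial = NULL) {
  env <- as.data.frame(env)
  n <- attr(as.dist(d), "Size")
  stopifnot(nrow(env) == n)
  res <- withSubSeed(seed, "dbrda", {
    do.call(rbind, lapply(names(env), function(v) {
      dat <- data.frame(x = env[[v]])
      fml <- if (is.null(partial)) d ~ x else d ~ x + Condition(z)
      if (!is.null(partial)) dat$z <- as.matrix(partial)
      m <- vegan::capscale(fml, data = dat)
      a <- vegan::anova.cca(m, permutations = n_perm)
      r2 <- vegan::RsquareAdj(m)$r.squared
      data.frame(variable = v, F = a$F[1], R2 = r2,
                 p = a$`Pr(>F)`[1])
    }))
  })
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < fdr
  joint <- NULL
  sig <- res$variable[res$significant]
  if (length(sig)) {
    if (length(sig) >= n) {
      warning("more significant variables than samples; joint model truncated")
      sig <- sig[seq_len(n - 2)]
    }
    mj <- vegan::capscale(d ~ ., data = env[, sig, drop = FALSE])
    ra <- vegan::RsquareAdj(mj)
    joint <- list(R2 = ra$r.squared, adj_R2 = ra$adj.r.squared,
                  variables = sig)
  }
  list(table = res, joint = joint)
}

#' Genetics-versus-environment explained variance of beta diversity
#'
#' Ranks SNPs by their beta-diversity association p-value, takes the top
#' k (k = the number of significant environmental variables), and
#' reports the joint dbRDA explained variance (plain and adjusted R2)
#' for the SNP set next to that of the environmental set.
#'
#' @param d community dissimilarity \code{dist}.
#' @param genotypes \linkS4class{GenotypeMatrix} (rows aligned with d).
#' @param beta_scan beta-diversity association data.frame (from
#'   \code{\link{betaDiversityScan}}).
#' @param env_scan result of \code{\link{dbrdaEnvScan}}.
#' @param env data.frame used for the env scan.
#' @param k number of top SNPs; defaults to the number of significant
#'   env variables.
#' @return list: k, snp (R2, adj_R2, variants), env (R2, adj_R2,
#'   variables).
#' @export
geneticsVsEnvVariance <- function(d, genotypes, beta_scan, env_scan, env,
                                  k = NULL) {
  sig <- env_scan$table$variable[env_scan$table$significant]
  if (is.null(k)) k <- length(sig)
  ord <- beta_scan[order(beta_scan$p), , drop = FALSE]
  k <- min(k, nrow(ord))
  snp_side <- list(R2 = 0, adj_R2 = 0, variants = character())
  env_side <- list(R2 = 0, adj_R2 = 0, variables = character())
  if (k > 0) {
    top <- ord$variant[seq_len(k)]
    G <- as.data.frame(dosages(genotypes)[, top, drop = FALSE])
    ms <- vegan::capscale(d ~ ., data = G)
    ra <- vegan::RsquareAdj(ms)
    snp_side <- list(R2 = ra$r.squared, adj_R2 = ra$adj.r.squared,
                     variants = top)
  }
  if (length(sig)) {
    me <- vegan::capscale(d ~ ., data = env[, sig, drop = FALSE])
    ra <- vegan::RsquareAdj(me)
    env_side <- list(R2 = ra$r.squared, adj_R2 = ra$adj.r.squared,
                     variables = sig)
  }
  list(k = k, snp = snp_side, env = env_side)
}
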