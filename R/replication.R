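#' Harmonize discovery and replication association records
#'
#' Matches records by (chrom, pos) and allele pair. When the replication
#' cohort's minor allele is the discovery cohort's major allele, the
#' replication beta is sign-flipped so both effects refer to the
#' discovery minor allele. Variants absent from the replication set, or
#' with an allele pair matching in neither orientation, are reported
#' unmatched.
#'
#' @param discovery,replication association data.frames carrying
#'   variant, chrom, pos, minor_allele, beta, p plus (for allele
#'   checking) ref/alt columns if available.
#' @param disc_variants,rep_variants optional variant metadata
#'   data.frames (from \code{\link{variantInfo}}) supplying ref/alt for
#'   each cohort.
#' @return list: \code{matched} data.frame (discovery columns plus
#'   rep_beta, rep_se, rep_p after harmonization), \code{unmatched}
#'   data.frame with a reason column.
#' @export
harmonizeVariants <- function(discovery, replication,
                              disc_variants = NULL, rep_variants = NULL) {
  alleles <- function(res, vtab) {
    if (!is.null(vtab)) {
      m <- vtab[match(res$variant, vtab$id), ]
      paste(pmin(m$ref, m$alt), pmax(m$ref, m$alt))
    } else rep(NA_character_, nrow(res))
  }
  dkey <- paste(discovery$chrom, discovery$pos)
  rkey <- paste(replication$chrom, replication$pos)
  hit <- match(dkey, rkey)
  da <- alleles(discovery, disc_variants)
  ra <- alleles(replication, rep_variants)
  reason <- rep(NA_character_, nrow(discovery))
  reason[is.na(hit)] <- "absent_in_replication"
  ok <- !is.na(hit)
  mism <- ok & !is.na(da) & !is.na(ra[hit]) & da != ra[hit]
  reason[mism] <- "allele_mismatch"
  ok <- ok & !mism
  m <- discovery[ok, , drop = FALSE]
  r <- replication[hit[ok], , drop = FALSE]
  flip <- m$minor_allele != r$minor_allele
  m$rep_beta <- ifelse(flip, -r$beta, r$beta)
  m$rep_se <- r$se
  m$rep_p <- r$p
  m$flipped <- flip
  list(matched = m,
       unmatched = cbind(discovery[!is.na(reason), , drop = FALSE],
                         reason = reason[!is.na(reason)]))
}

#' Assess same-direction replication
#'
#' An association replicates iff its replication p is below alpha and
#' the replication effect has the same sign as the discovery effect for
#' the harmonized minor allele. Zero effects are a direction tie,
#' counted not replicated.
#'
#' @param matched matched data.frame from
#'   \code{\link{harmonizeVariants}}.
#' @param alpha nominal replication level.
#' @return list: \code{matched} with a \code{replicated} flag,
#'   \code{n_testable}, \code{n_replicated}, \code{replication_rate}.
#' @export
assessReplication <- function(matched, alpha = 0.05) {
  stopifnot(nrow(matched) > 0)
  tie <- !is.na(matched$beta) & !is.na(matched$rep_beta) &
    (matched$beta == 0 | matched$rep_beta == 0)
  if (any(tie)) message(sum(tie), " direction tie(s) counted not replicated")
  rep <- !is.na(matched$rep_p) & matched$rep_p < alpha &
    sign(matched$rep_beta) == sign(matched$beta) & !tie
  matched$replicated <- rep
  list(matched = matched, n_testable = nrow(matched),
       n_replicated = sum(rep),
       replication_rate = sum(rep) / nrow(matched))
}

#' Resampling-based expected replication rate
#'
#' Draws \code{n_draw} associations uniformly without replacement from
#' the candidate pool per iteration, assesses same-direction replication
#' in each draw, and averages the replicated counts over iterations; the
#' expected rate is that mean count divided by \code{n_draw}.
#'
#' @param pool matched data.frame (candidate testable associations, e.g.
#'   all discovery-suggestive associations testable in replication).
#' @param n_draw draw size per iteration.
#' @param n_iters number of iterations (default 10).
#' @param alpha nominal replication level.
#' @param seed RNG seed.
#' @return list: expected_rate, expected_count, per_iter counts.
#' @export
resamplingExpectedRate <- function(pool, n_draw, n_iters = 10,
                                   alpha = 0.05, seed = 1L) {
  if (nrow(pool) < n_draw)
    stop("candidate pool (", nrow(pool), ") smaller than n_draw (", n_draw, ")")
  counts <- withSubSeed(seed, "resample", {
    vapply(seq_len(n_iters), function(i) {
      draw <- pool[sample.int(nrow(pool), n_draw), , drop = FALSE]
      assessReplication(draw, alpha)$n_replicated
    }, numeric(1))
  })
  list(expected_rate = mean(counts) / n_draw,
       expected_count = mean(counts), per_iter = counts)
}

#' Chi-square enrichment of observed over expected replication
#'
#' Builds the 2x2 table [observed replicated, observed non-replicated;
#' expected replicated = rate * n, expected non-replicated =
#' (1 - rate) * n] and computes the Pearson chi-square with Yates
#' continuity correction (1 df); p is the upper tail of chi-square(1)
#' (the one-sided enrichment reading).
#'
#' @param n_replicated,n_testable observed counts.
#' @param expected_rate expected replication rate in (0, 1).
#' @return list: chi2, df, p, plus the report fields (rates, counts).
#' @export
chi2Enrichment <- function(n_replicated, n_testable, expected_rate) {
  stopifnot(n_testable > 0, n_replicated >= 0, n_replicated <= n_testable)
  if (expected_rate <= 0 || expected_rate >= 1)
    stop("expected_rate must lie strictly in (0, 1)")
  e1 <- expected_rate * n_testable
  tab <- rbind(observed = c(n_replicated, n_testable - n_replicated),
               expected = c(e1, n_testable - e1))
  if (any(colSums(tab) == 0)) stop("degenerate expected counts")
  # Yates-corrected Pearson chi-square, correction floored so the
  # statistic is never negative
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- pmax(abs(tab - E) - 0.5, 0)
  chi2 <- sum(adj^2 / E)
  list(chi2 = chi2, df = 1L,
       p = pchisq(chi2, df = 1, lower.tail = FALSE),
       n_replicated = n_replicated, n_testable = n_testable,
       replication_rate = n_replicated / n_testable,
       expected_rate = expected_rate)
}

#' Full replication report
#'
#' Convenience wrapper: harmonize, assess, estimate the expected rate by
#' resampling from the candidate pool, and run the enrichment test. The
#' resampling estimate is an unbiased Monte-Carlo estimate of the pool's
#' own replication rate; when a small draw budget returns a degenerate
#' estimate (0 or 1) the exact pool rate is used instead, recorded in
#' \code{expected_source}.
#'
#' @param discovery_hits matched+assessed discovery-significant set
#'   (from \code{\link{assessReplication}}).
#' @param pool matched candidate pool for the resampling expectation.
#' @param n_iters resampling iterations.
#' @param alpha replication level.
#' @param seed RNG seed.
#' @return list of class \code{mgwasReplicationReport}.
#' @export
replicationReport <- function(discovery_hits, pool, n_iters = 10,
                              alpha = 0.05, seed = 1L) {
  exp <- resamplingExpectedRate(pool, n_draw = discovery_hits$n_testable,
                                n_iters = n_iters, alpha = alpha,
                                seed = seed)
  rate <- exp$expected_rate
  source <- "resampling"
  if (rate <= 0 || rate >= 1) {
    rate <- assessReplication(pool, alpha)$replication_rate
    source <- "pool"
  }
  enr <- chi2Enrichment(discovery_hits$n_replicated,
                        discovery_hits$n_testable, rate)
  structure(c(enr, list(n_resample_iters = n_iters,
                        expected_source = source)),
            class = "mgwasReplicationReport")
}

#' @export
print.mgwasReplicationReport <- function(x, ...) {
  cat(sprintf(
    "replication: %d/%d (%.2f%%) vs expected %.2f%%; chi2 = %.3f, df = 1, p = %.3g\n",
    x$n_replicated, x$n_testable, 100 * x$replication_rate,
    100 * x$expected_rate, x$chi2, x$p))
  invisible(x)
}

#' Cross-niche concordance of associations
#'
#' For each association significant at \code{gw_alpha} in niche A,
#' checks whether niche B shows p < \code{nominal_alpha} with the same
#' minor-allele effect direction (after harmonization on the shared
#' panel). Associations whose trait is absent in niche B are excluded
#' and counted separately.
#'
#' @param results_a,results_b association data.frames for the two
#'   niches (same variant panel).
#' @param gw_alpha discovery threshold applied to niche A.
#' @param nominal_alpha concordance threshold in niche B.
#' @return list: \code{table} (per-association p/beta comparison with a
#'   concordant flag), \code{concordance} fraction,
#'   \code{n_trait_absent}.
#' @export
crossNicheConcordance <- function(results_a, results_b, gw_alpha = 5e-8,
                                  nominal_alpha = 0.05) {
  hits <- results_a[!is.na(results_a$p) & results_a$p < gw_alpha, ,
                    drop = FALSE]
  keyb <- paste(results_b$variant, results_b$trait)
  keya <- paste(hits$variant, hits$trait)
  absent <- !hits$trait %in% results_b$trait
  hit2 <- match(keya, keyb)
  use <- !absent & !is.na(hit2)
  b <- results_b[hit2[use], , drop = FALSE]
  a <- hits[use, , drop = FALSE]
  flip <- a$minor_allele != b$minor_allele
  bbeta <- ifelse(flip, -b$beta, b$beta)
  conc <- !is.na(b$p) & b$p < nominal_alpha & sign(bbeta) == sign(a$beta)
  tab <- data.frame(variant = a$variant, trait = a$trait,
                    beta_a = a$beta, p_a = a$p,
                    beta_b = bbeta, p_b = b$p, concordant = conc)
  list(table = tab,
       concordance = if (nrow(tab)) mean(conc) else NA_real_,
       n_trait_absent = sum(absent))
}
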