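test_that("variant QC applies HWE, MAF and call-rate rules", {
  # exact HWE proportions (25, 50, 25): chi-square 0, kept
  d1 <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  # (30, 40, 30): allele freq 0.5, expected (25, 50, 25), chi2 = 4
  d2 <- c(rep(0, 30), rep(1, 40), rep(2, 30))
  chi2_oracle <- (30 - 25)^2 / 25 + (40 - 50)^2 / 50 + (30 - 25)^2 / 25
  expect_equal(chi2_oracle, 4)
  expect_equal(mgwas:::hweTest(d2)$stat, chi2_oracle)
  d3 <- c(rep(1, 2), rep(0, 98))        # MAF 0.01, below a 2% floor
  d4 <- c(rep(NA, 5), rep(c(0, 1, 2), length.out = 95))  # call rate 95%
  g <- makeGenotypes(cbind(v1 = d1, v2 = d2, v3 = d3, v4 = d4))
  qc <- variantQC(g, scanConfig(maf_min = 0.02))
  expect_true(qc$pass[1])
  expect_true(qc$pass[2])   # p = 0.0455 > 1e-5
  expect_false(qc$pass[3]); expect_equal(qc$reason[3], "maf")
  expect_false(qc$pass[4]); expect_equal(qc$reason[4], "call_rate")
  # monomorphic: excluded with reason maf, no error
  g5 <- makeGenotypes(cbind(v1 = d1, v5 = rep(0, 100)))
  qc5 <- variantQC(g5)
  expect_false(qc5$pass[2]); expect_equal(qc5$reason[2], "maf")
})

test_that("HWE exact test matches enumeration on a small case", {
  # n = 5 diploids, 4 minor alleles: enumerate het counts {0, 2, 4}
  p_oracle <- local({
    nA <- 4; n <- 5
    prob <- function(h) {
      naa <- (nA - h) / 2; nbb <- n - h - naa
      choose(n, naa) * choose(n - naa, h) * 2^h /
        choose(2 * n, nA) * 1
    }
    pr <- vapply(c(0, 2, 4), prob, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[2] + 1e-12])   # observed het = 2
  })
  dos <- c(2, 1, 1, 0, 0)
  expect_equal(mgwas:::hweExactTest(dos)$p, p_oracle, tolerance = 1e-10)
})

test_that("perfect fit reports the exact slope and floored p", {
  d <- cbind(v1 = c(0, 0, 1, 1, 2, 2))
  g <- makeGenotypes(d)
  s <- linearScan(g, 2 * d[, 1], trait_id = "y")
  expect_equal(s$beta, 2)
  expect_equal(s$p, .Machine$double.xmin)
})

test_that("scan estimates equal the normal-equations oracle exactly", {
  set.seed(51)
  n <- 150
  d <- randomDosage(n, runif(8, 0.1, 0.5))
  d[sample(n, 10), 3] <- NA          # exercise the complete-case path
  g <- makeGenotypes(d)
  covar <- cbind(age = rnorm(n), pc1 = rnorm(n))
  y <- rnorm(n) + 0.3 * dosages(g)[, 5]
  y[c(2, 7)] <- NA
  s <- linearScan(g, y, covar, trait_id = "y")
  for (j in c(1, 3, 5)) {
    x <- dosages(g)[, j]
    use <- !is.na(y) & !is.na(x)
    X <- cbind(1, x[use], covar[use, ])
    b <- solve(crossprod(X), crossprod(X, y[use]))
    e <- y[use] - X %*% b
    sigma2 <- sum(e^2) / (nrow(X) - ncol(X))
    se <- sqrt(sigma2 * solve(crossprod(X))[2, 2])
    expect_equal(s$beta[j], b[2], tolerance = 1e-10)
    expect_equal(s$se[j], se, tolerance = 1e-10)
    expect_equal(s$n[j], sum(use))
  }
})

test_that("null linear scan has calibrated type-I error", {
  set.seed(52)
  g <- makeGenotypes(randomDosage(300, runif(1000, 0.1, 0.5)))
  s <- linearScan(g, rnorm(300), trait_id = "null")
  frac <- mean(s$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("effects are reported per minor-allele copy; relabelling flips the sign", {
  set.seed(53)
  d <- randomDosage(200, 0.3)
  g <- makeGenotypes(d)
  y <- 0.5 * d[, 1] + rnorm(200)
  b_minor <- linearScan(g, y)$beta
  # complementing the dosage and swapping the allele labels re-polarises
  # to the same in-sample minor allele: identical record
  v <- variantInfo(g)
  v$minor_allele <- "A"
  g_flip <- GenotypeMatrix(2 - d, v[, c("id", "chrom", "pos", "ref",
                                        "alt", "minor_allele")])
  expect_equal(linearScan(g_flip, y)$beta, b_minor)
  # regression on the major-allele count gives exactly -beta
  b_major <- coef(lm(y ~ I(2 - d[, 1])))[2]
  expect_equal(unname(b_major), -b_minor, tolerance = 1e-12)
})

test_that("rank-deficient covariates are dropped with a warning, constant traits skipped", {
  set.seed(54)
  g <- makeGenotypes(randomDosage(100, c(0.2, 0.4)))
  covar <- cbind(a = rnorm(100))
  covar <- cbind(covar, b = 2 * covar[, "a"])
  expect_warning(s <- linearScan(g, rnorm(100), covar), "collinear")
  expect_equal(nrow(s), 2)
  expect_warning(s0 <- linearScan(g, rep(1, 100)), "constant")
  expect_equal(nrow(s0), 0)
})

test_that("logistic scan matches glm and recovers planted log-odds", {
  set.seed(55)
  n <- 2000
  d <- randomDosage(n, c(0.3, 0.2, 0.4))
  eta <- -1 + 0.5 * d[, 1]
  y <- rbinom(n, 1, plogis(eta))
  g <- makeGenotypes(d)
  s <- logisticScan(g, y)
  f <- glm(y ~ d[, 1], family = binomial())
  expect_equal(s$beta[1], unname(coef(f)[2]), tolerance = 1e-6)
  expect_equal(s$se[1], unname(summary(f)$coefficients[2, 2]),
               tolerance = 1e-6)
  expect_lt(abs(s$beta[1] - 0.5), 3 * s$se[1])
})

test_that("logistic null scan is calibrated and separation is flagged", {
  set.seed(56)
  n <- 400
  g <- makeGenotypes(randomDosage(n, runif(500, 0.15, 0.5)))
  y <- rbinom(n, 1, 0.3)
  s <- logisticScan(g, y)
  frac <- mean(s$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  # perfectly separating variant
  ysep <- as.integer(dosages(g)[, 1] > 0)
  ssep <- logisticScan(subsetVariants(g, "v001"), ysep)
  expect_false(ssep$converged[1])
  expect_true(is.na(ssep$p[1]))
  # single-class outcome: skipped with warning
  expect_warning(s1 <- logisticScan(g, rep(1, n)), "single class")
  expect_equal(nrow(s1), 0)
})

test_that("Shannon diversity matches closed forms", {
  a <- rbind(u = rep(0.1, 10),
             s = c(1, rep(0, 9)),
             m = c(0.25, 0.75, rep(0, 8)))
  colnames(a) <- paste0("t", 1:10)
  prof <- TaxaProfile(a)
  h <- alphaDiversity(prof)
  expect_equal(unname(h["u"]), log(10), tolerance = 1e-12)
  expect_equal(unname(h["s"]), 0)
  expect_equal(unname(h["m"]), 0.5623351, tolerance = 1e-6)
  # all-zero sample is NA
  a0 <- rbind(a, z = rep(0, 10))
  expect_true(is.na(alphaDiversity(TaxaProfile(a0))["z"]))
})

test_that("Pillai trace agrees with stats::manova and reduces to the univariate F", {
  set.seed(57)
  n <- 120
  d <- randomDosage(n, c(0.3, 0.45))
  g <- makeGenotypes(d)
  covar <- cbind(c1 = rnorm(n))
  Y <- cbind(rnorm(n) + 0.4 * d[, 1], rnorm(n))
  s <- betaDiversityScan(g, Y, covar)
  for (j in 1:2) {
    fit <- manova(Y ~ covar + d[, j])
    sm <- summary(fit, test = "Pillai")$stats
    expect_equal(s$stat[j], sm["d[, j]", "Pillai"], tolerance = 1e-8)
    expect_equal(s$p[j], sm["d[, j]", "Pr(>F)"], tolerance = 1e-8)
  }
  # single-axis reduction identity
  s1 <- betaDiversityScan(g, Y[, 1, drop = FALSE], covar)
  lin <- linearScan(g, Y[, 1], covar)
  expect_equal(s1$p, lin$p, tolerance = 1e-8)
})

test_that("null Pillai p-values are uniform", {
  set.seed(58)
  g <- makeGenotypes(randomDosage(150, runif(400, 0.1, 0.5)))
  Y <- matrix(rnorm(300), 150)
  s <- betaDiversityScan(g, Y)
  ks <- suppressWarnings(ks.test(s$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("genomic inflation is anchored by construction cases", {
  p <- (seq_len(1001) - 0.5) / 1001   # exact uniform quantiles
  expect_equal(genomicInflation(p = p), 1.0, tolerance = 1e-3)
  expect_equal(genomicInflation(stat = rep(0.90988, 200)), 2.0,
               tolerance = 1e-4)
  expect_error(genomicInflation(), "need p-values")
  expect_warning(genomicInflation(p = runif(10)), "fewer than 100")
})

test_that("study-wide thresholds reproduce the Bonferroni arithmetic", {
  expect_equal(signif(significanceThresholds(5e-8, 1583)$study_wide, 3),
               3.16e-11)
  expect_equal(signif(significanceThresholds(5e-8, 1685)$study_wide, 3),
               2.97e-11)
  expect_equal(significanceThresholds(5e-8, 1)$study_wide, 5e-8)
})

test_that("clumping follows the window-and-r2 rule", {
  set.seed(59)
  n <- 200
  x1 <- rbinom(n, 2, 0.3)
  x2 <- ifelse(runif(n) < 0.85, x1, rbinom(n, 2, 0.3))  # r2 ~ 0.5-0.8
  x3 <- rbinom(n, 2, 0.3)
  d <- cbind(v1 = x1, v2 = x2, v3 = x1)
  g <- makeGenotypes(d, pos = c(1e6, 1.5e6, 3.5e6))  # v3 2.5 Mb away
  res <- data.frame(variant = c("v1", "v2", "v3"), chrom = "chr1",
                    pos = c(1e6, 1.5e6, 3.5e6), minor_allele = "G",
                    maf = 0.3, trait = "t", n = n, beta = 1, se = 0.1,
                    stat = 10, p = c(1e-10, 1e-6, 1e-7), model = "linear")
  cl <- clumpAssociations(res, g)
  expect_true(cl$is_index[cl$variant == "v1"])
  # v2: within window and correlated with v1 -> absorbed
  expect_equal(cl$index[cl$variant == "v2"], "v1")
  # v3: identical genotypes but outside the 1 Mb window -> own index
  expect_true(cl$is_index[cl$variant == "v3"])
  # single record is its own index
  one <- clumpAssociations(res[1, ], g)
  expect_true(one$is_index)
  # cross-trait locus clumping collapses to best-p per variant first
  res2 <- rbind(res, transform(res, trait = "t2", p = p / 10))
  loci <- clumpAssociations(res2, g, scope = "variants")
  expect_equal(sort(unique(loci$index)), c("v1", "v3"))
})
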