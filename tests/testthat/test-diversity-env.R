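test_that("Bray-Curtis matches the direct formula and aggregates genera", {
  a <- rbind(s1 = c(0.2, 0.8), s2 = c(0.5, 0.5), s3 = c(0.2, 0.8))
  colnames(a) <- c("t1", "t2")
  d <- brayCurtis(TaxaProfile(a), level = "taxon")
  m <- as.matrix(d)
  expect_equal(m["s1", "s2"], 0.3, tolerance = 1e-12)
  expect_equal(m["s1", "s3"], 0)
  # disjoint supports
  b <- rbind(s1 = c(0.6, 0, 0.4, 0), s2 = c(0, 0.3, 0, 0.7))
  colnames(b) <- paste0("t", 1:4)
  expect_equal(as.vector(brayCurtis(TaxaProfile(b), "taxon")), 1)
  # random profiles against the formula oracle
  set.seed(71)
  r <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  r <- r / rowSums(r)
  dd <- as.matrix(brayCurtis(TaxaProfile(r), "taxon"))
  for (i in 1:7) for (j in (i + 1):8) {
    oracle <- sum(abs(r[i, ] - r[j, ])) / sum(r[i, ] + r[j, ])
    expect_equal(dd[i, j], oracle, tolerance = 1e-12)
  }
  # genus-level aggregation: two taxa of one genus merge
  tax <- c(t1 = "k__B|g__g1|s__t1", t2 = "k__B|g__g1|s__t2",
           t3 = "k__B|g__g2|s__t3")
  p3 <- rbind(s1 = c(0.2, 0.3, 0.5), s2 = c(0.5, 0.0, 0.5))
  colnames(p3) <- names(tax)
  dg <- as.matrix(brayCurtis(TaxaProfile(p3, tax), "genus"))
  expect_equal(dg["s1", "s2"], 0, tolerance = 1e-12)  # both (0.5, 0.5)
})

test_that("classical scaling reproduces Euclidean configurations", {
  set.seed(72)
  pts <- matrix(rnorm(40), 20, 2)
  d <- dist(pts)
  fit <- pcoa(d, n_axes = 2)
  # Procrustes: recovered axes equal original points up to rotation
  pr <- vegan::procrustes(pts, fit$axes, symmetric = FALSE)
  expect_lt(pr$ss / sum(scale(pts, scale = FALSE)^2), 1e-8)
  # eigenvalue conservation: sum equals centred trace
  A <- -0.5 * as.matrix(d)^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  expect_equal(sum(fit$eigenvalues), sum(diag(G)), tolerance = 1e-10)
  # duplicated samples land on identical coordinates
  pts2 <- rbind(pts, pts[1, ])
  fit2 <- pcoa(dist(pts2), n_axes = 2)
  expect_equal(fit2$axes[21, ], fit2$axes[1, ], tolerance = 1e-8)
})

test_that("PERMANOVA agrees with vegan::adonis2 and brute-force enumeration", {
  set.seed(73)
  a <- matrix(runif(60), 12, 5)
  a <- a / rowSums(a)
  grp <- rep(c("x", "y"), each = 6)
  d <- vegan::vegdist(a, "bray")
  mine <- permanova(d, factor(grp), n_perm = 199, seed = 3)
  ref <- vegan::adonis2(d ~ grp, permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  # exhaustive oracle on n = 6: exact permutation p
  set.seed(74)
  b <- matrix(runif(24), 6, 4); b <- b / rowSums(b)
  g6 <- factor(rep(c("x", "y"), each = 3))
  d6 <- vegan::vegdist(b, "bray")
  # enumerate via recursive permutations of 1:6
  permute_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute_all(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  P <- permute_all(1:6)
  fstat <- function(perm) {
    permanova(d6, g6[perm], n_perm = 1, seed = 1)$pseudo_F
  }
  Fobs <- fstat(1:6)
  Fall <- vapply(P, fstat, numeric(1))
  exact_p <- mean(Fall >= Fobs - 1e-12)
  mc <- permanova(d6, g6, n_perm = 1999, seed = 5)
  expect_lt(abs(mc$p - exact_p), 0.05)
  # two well-separated clusters: maximal significance
  sep <- rbind(matrix(runif(40, 0, 0.1), 10), matrix(runif(40, 5, 6), 10))
  dsep <- dist(sep)
  ps <- permanova(dsep, factor(rep(1:2, each = 10)), n_perm = 199, seed = 6)
  expect_equal(ps$p, 1 / 200)
})

test_that("alpha-diversity comparison detects shifts and matches rank oracle", {
  set.seed(75)
  mkprof <- function(shift) {
    z <- matrix(exp(rnorm(100 * 30, shift, 1)), 100, 30)
    z <- z / rowSums(z)
    dimnames(z) <- list(sprintf("s%03d", 1:100), sprintf("t%02d", 1:30))
    TaxaProfile(z)
  }
  pa <- mkprof(0)
  same <- alphaCompare(pa, pa)
  expect_gt(same$p, 0.99)
  # concentrate one group on few taxa: lower Shannon
  z2 <- abundances(mkprof(0))
  z2[, 1] <- z2[, 1] + 5
  z2 <- z2 / rowSums(z2)
  lo <- TaxaProfile(z2)
  cmp <- alphaCompare(pa, lo)
  expect_lt(cmp$p, 1e-10)
  expect_gt(cmp$mean_a, cmp$mean_b)
  # naive O(n^2) rank oracle equals rank()
  x <- rnorm(50); x[c(3, 7)] <- x[c(4, 8)]  # ties
  naive <- vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
  expect_equal(naive, rank(x))
})

test_that("collinearity pruning drops one member per offending pair", {
  set.seed(76)
  env <- data.frame(a = rnorm(100))
  env$b <- env$a                      # duplicate
  env$c <- rnorm(100)                 # independent
  env$k <- rep(1, 100)                # constant
  pr <- pruneCollinearEnv(env)
  expect_setequal(pr$kept, c("a", "c"))
  expect_true("k" %in% pr$dropped$variable)
  expect_true("b" %in% pr$dropped$variable)
  # all mutually independent: everything kept
  ind <- as.data.frame(matrix(rnorm(3000), 100, 30))
  expect_equal(length(pruneCollinearEnv(ind)$kept), 30)
})

test_that("a 423-variable panel with 83 collinear partners prunes to 340", {
  set.seed(77)
  n <- 400
  base <- matrix(rnorm(n * 340), n, 340)
  partners <- vapply(1:83, function(j)
    0.9 * base[, j] + sqrt(1 - 0.81) * rnorm(n), numeric(n))
  env <- as.data.frame(cbind(base, partners))
  names(env) <- sprintf("e%03d", seq_len(423))
  pr <- pruneCollinearEnv(env, rho_limit = 0.6)
  expect_equal(length(pr$kept), 340)
})

test_that("dbRDA explained variance equals multivariate regression R2 on Euclidean data", {
  set.seed(78)
  n <- 60
  Y <- matrix(rnorm(n * 3), n, 3)
  x <- rnorm(n)
  Y[, 1] <- Y[, 1] + 0.8 * x
  d <- dist(Y)
  scan <- dbrdaEnvScan(d, data.frame(x = x), n_perm = 199, seed = 8)
  # multivariate regression R2: tr(SS_fit) / tr(SS_tot) on centred Y
  Yc <- scale(Y, scale = FALSE)
  H <- tcrossprod(qr.Q(qr(cbind(1, x))))
  r2_oracle <- sum((H %*% Yc)^2) / sum(Yc^2)
  expect_equal(scan$table$R2[1], r2_oracle, tolerance = 1e-8)
  expect_true(scan$table$significant[1])
  expect_equal(scan$joint$variables, "x")
})

test_that("orthogonal predictors are non-significant and R2 is additive on toys", {
  set.seed(79)
  n <- 80
  Y <- matrix(rnorm(n * 4), n, 4)
  x1 <- Y[, 1] - mean(Y[, 1])
  x2 <- resid(lm(Y[, 2] ~ x1))        # exactly orthogonal drivers
  noise <- rnorm(n)
  d <- dist(Y)
  scan <- dbrdaEnvScan(d, data.frame(x1 = x1, x2 = x2, z = noise),
                       n_perm = 199, seed = 9)
  tab <- scan$table
  expect_false(tab$significant[tab$variable == "z"])
  # explained fractions of disjoint orthogonal predictors are additive
  joint <- vegan::capscale(d ~ x1 + x2)
  r12 <- vegan::RsquareAdj(joint)$r.squared
  expect_lt(abs(r12 - sum(tab$R2[tab$variable %in% c("x1", "x2")])), 1e-6)
})

test_that("top-SNP variance comparison behaves under construction", {
  set.seed(80)
  co <- simulateCohort(simulationConfig(
    n_discovery = 250, n_replication = 0, n_snps = 120, n_taxa = 20,
    n_planted = 8, effect_size_range = c(1.2, 1.5), n_clusters = 0,
    zero_inflation = 0, n_env = 6, n_collinear_pairs = 0,
    env_effect_size = 0, seed = 81))
  g <- co$discovery$genotypes
  bc <- brayCurtis(co$discovery$taxa)
  ax <- pcoa(bc, 2)$axes
  bs <- betaDiversityScan(g, ax)
  es <- dbrdaEnvScan(bc, co$discovery$covariates, n_perm = 99, seed = 82)
  cmp <- geneticsVsEnvVariance(bc, g, bs, es, co$discovery$covariates,
                               k = 5)
  # community structure is driven only by planted SNPs, not environment
  expect_gt(cmp$snp$R2, cmp$env$R2)
  # k = 0: both sides zero
  cmp0 <- geneticsVsEnvVariance(bc, g, bs,
                                list(table = data.frame(variable = character(),
                                                        significant = logical())),
                                co$discovery$covariates, k = 0)
  expect_equal(cmp0$snp$R2, 0)
  expect_equal(cmp0$env$R2, 0)
  # adding a perfectly redundant SNP leaves cumulative R2 unchanged
  d2 <- cbind(dosages(g)[, 1:3], dup = dosages(g)[, 3])
  colnames(d2) <- c("a", "b", "c", "dup")
  G <- as.data.frame(d2)
  r3 <- vegan::RsquareAdj(vegan::capscale(bc ~ a + b + c, data = G))$r.squared
  r4 <- vegan::RsquareAdj(vegan::capscale(bc ~ a + b + c + dup,
                                          data = G))$r.squared
  expect_lt(abs(r4 - r3), 1e-6)
})
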