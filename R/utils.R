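# Internal helpers shared across modules.

# Derive a reproducible 31-bit sub-seed from a master seed and a stream
# name, so that every randomised stage draws from its own named substream
# and adding a stage never perturbs earlier ones.
subSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

withSubSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(subSeed(seed, stream))
  expr
}

# Hardy-Weinberg test from a dosage vector (0/1/2 counts of one allele).
# method "chisq": Pearson goodness-of-fit on the three genotype classes
# with allele frequency estimated from the data (1 df). method "exact":
# the standard exact test summing haplotype-count probabilities no more
# likely than the observed heterozygote count.
hweTest <- function(dosage, method = c("chisq", "exact")) {
  method <- match.arg(method)
  dosage <- dosage[!is.na(dosage)]
  n0 <- sum(dosage == 0); n1 <- sum(dosage == 1); n2 <- sum(dosage == 2)
  n <- n0 + n1 + n2
  if (n == 0) return(list(stat = NA_real_, p = NA_real_))
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(list(stat = 0, p = 1))
  if (method == "chisq") {
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    list(stat = NA_real_, p = hweExactP(n1, 2 * n2 + n1, n))
  }
}

# Exact HWE p-value given observed het count nAB and minor-allele total nA
# over n diploids (Wigginton-style enumeration).
hweExactP <- function(nAB, nA, n) {
  nA <- min(nA, 2L * n - nA)
  hets <- seq(nA %% 2, nA, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - h - naa
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(nAB, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# Vectorised HWE chi-square p across the columns of a dosage matrix.
hweChisqVec <- function(d) {
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  stat <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  out <- pchisq(stat, df = 1, lower.tail = FALSE)
  out[!is.na(p) & (p == 0 | p == 1)] <- 1
  out[n == 0] <- NA
  out
}

# Exact-test wrapper on a dosage vector.
hweExactTest <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  n1 <- sum(dosage == 1)
  nA <- sum(dosage)
  n <- length(dosage)
  if (n == 0) return(list(stat = NA_real_, p = NA_real_))
  list(stat = NA_real_, p = hweExactP(n1, nA, n))
}

# Rank-based AUC of score for binary outcome (probability a random case
# outranks a random control; ties get half credit).
rankAuc <- function(score, outcome) {
  stopifnot(length(score) == length(outcome))
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Trapezoidal ROC-integral AUC, used as an independent cross-check of
# rankAuc in the test suite.
trapezoidAuc <- function(score, outcome) {
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(score[outcome == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[outcome == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Write a table as TSV with sample ids in the first column
#' @param x matrix or data.frame with sample ids as rownames.
#' @param path output file.
#' @param id_col name of the identifier column.
#' @export
writeTsv <- function(x, path, id_col = "sample_id") {
  df <- as.data.frame(x, check.names = FALSE)
  out <- cbind(setNames(data.frame(rownames(df)), id_col), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
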