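# Shared fixtures, built in code at test time.

options(coexBench.quiet = TRUE)

# small random expression matrix with dimnames
makeExpr <- function(genes = 10, samples = 8, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(genes * samples, sd = sd), genes, samples,
                dimnames = list(sprintf("G%03d", seq_len(genes)),
                                sprintf("S%03d", seq_len(samples))))
    m
  })
}

writeTsvFixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# a small typed phenotype table
makePheno <- function(n = 8, seed = 1) {
  withr::with_seed(seed, data.frame(
    GENDER = factor(sample(c("F", "M"), n, replace = TRUE),
                    levels = c("F", "M")),
    SMTSISCH = runif(n, 0, 1500),
    SMGEBTCH = factor(sample(paste0("B", 1:3), n, replace = TRUE)),
    row.names = sprintf("S%03d", seq_len(n))))
}

# brute-force Spearman oracle: rank both vectors, Pearson-correlate
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rs <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(rs) >= 1) 0 else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(rs = rs, p = p)
}

# exhaustive Mann-Whitney oracle with half credit for ties
aucOracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# step-by-step replay of the calibration loop (independent of the package's
# internal implementation)
calibrationOracle <- function(conf, low0 = 0.01, high0 = 0.7,
                              stepLow = 0.005, stepHigh = 0.05,
                              balanceTol = 1.25, maxIter = 10000) {
  low <- low0; high <- high0
  trajectory <- list()
  for (i in seq_len(maxIter)) {
    nT <- sum(conf > high); nF <- sum(conf < low)
    trajectory[[i]] <- c(low = low, high = high, nT = nT, nF = nF)
    if (max(nT, nF) / max(1, min(nT, nF)) <= balanceTol)
      return(list(status = "balanced", cutoffFalse = low, cutoffTrue = high,
                  nTrue = nT, nFalse = nF, iterations = i - 1,
                  trajectory = trajectory))
    if (nT > nF) low <- low + stepLow else high <- high - stepHigh
    if (low >= high || low < 0 || low > 1 || high < 0 || high > 1)
      return(list(status = "failed", cutoffFalse = low, cutoffTrue = high,
                  nTrue = nT, nFalse = nF, iterations = i,
                  trajectory = trajectory))
  }
  list(status = "maxiter", trajectory = trajectory)
}

# small synthetic dataset for pipeline-level tests
smallSynthetic <- function(seed = 1, ...) {
  generateSynthetic(syntheticConfig(
    nGenes = 300, nSamples = 60, nTrueEdges = 40, nFalseEdges = 40,
    nFillerEdges = 1500, seed = seed, ...))
}
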