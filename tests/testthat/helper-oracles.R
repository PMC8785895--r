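# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths (sum-formula
# Pearson, explicit double loops) so that agreement is informative.

# Pearson correlation from raw sums.
bfPearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# Full correlation matrix by per-pair loops.
bfFcMatrix <- function(x) {
  k <- ncol(x)
  out <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- bfPearson(x[, i], x[, j])
    }
  }
  out
}

# Node variability by an explicit double loop over window pairs applied to
# a plain list of windowed matrices.
bfNodeVariability <- function(mats, k) {
  nT <- length(mats)
  rs <- c()
  for (i in seq_len(nT - 1)) {
    for (j in (i + 1):nT) {
      rs <- c(rs, bfPearson(mats[[i]][k, -k], mats[[j]][k, -k]))
    }
  }
  1 - mean(rs)
}

# Random time-series fixture with labelled columns.
randomTs <- function(nVol, nRoi, seed, id = "toy", trS = 2) {
  set.seed(seed)
  m <- matrix(rnorm(nVol * nRoi), nVol, nRoi,
              dimnames = list(NULL, sprintf("R%02d", seq_len(nRoi))))
  TimeSeriesMatrix(id, m, trS)
}

# Plain list of windowed matrices recomputed from scratch (0-based starts).
bfWindowMatrices <- function(ts, widthVol, stepVol) {
  x <- tsMatrix(ts)
  starts <- seq(0, nrow(x) - widthVol, by = stepVol)
  lapply(starts, function(s) bfFcMatrix(x[(s + 1):(s + widthVol), ]))
}

# Phenotype table generator for regression-level tests (no time series).
randomMetricsTable <- function(n, seed, nSites = 2) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    diagnosis = rep(c("MDD", "HC"), length.out = n),
    age = runif(n, 18, 65),
    sex = sample(c("male", "female"), n, replace = TRUE),
    education = runif(n, 6, 20),
    site = sample(sprintf("site%02d", seq_len(nSites)), n, replace = TRUE),
    mean_fd = runif(n, 0.02, 0.15),
    stringsAsFactors = FALSE)
}
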