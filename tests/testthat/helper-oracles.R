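# Independent, deliberately naive reference implementations used as
# oracles.  These loop sample-by-sample and evaluate the defining
# formulas directly; they share no code with the package internals.

# fuzzy-rank fusion: per-sample, per-classifier loop over the defining
# sums, penalties substituted term by term
oracleGompertzPredict <- function(dc, topM, literal = FALSE) {
  N <- dim(dc)[1]; X <- dim(dc)[2]; Y <- dim(dc)[3]
  penaltyFR <- 1 - exp(-1)
  pred <- integer(N)
  for (i in seq_len(N)) {
    frsum <- numeric(Y); conf <- numeric(Y)
    for (n in seq_len(X)) {
      row <- dc[i, n, ]
      o <- order(-row, seq_len(Y))
      rp <- integer(Y); rp[o] <- seq_len(Y)
      for (y in seq_len(Y)) {
        if (rp[y] <= topM) {
          frsum[y] <- frsum[y] + (1 - exp(-exp(-2 * row[y])))
          conf[y] <- conf[y] + row[y]
        } else {
          frsum[y] <- frsum[y] + penaltyFR  # conf contribution is 0
        }
      }
    }
    ccf <- if (literal) conf / X else 1 - conf / X
    pred[i] <- which.min(frsum * ccf)
  }
  pred
}

# weighted average: scalar loop
oracleWeightedPredict <- function(dc, w) {
  N <- dim(dc)[1]; X <- dim(dc)[2]; Y <- dim(dc)[3]
  pred <- integer(N)
  for (i in seq_len(N)) {
    fused <- numeric(Y)
    for (y in seq_len(Y))
      fused[y] <- sum(w * dc[i, , y]) / sum(w)
    pred[i] <- which.max(fused)
  }
  pred
}

# closed-form lambda-measure of an arbitrary subset
oracleSubsetMeasure <- function(subset, g, lambda) {
  if (length(subset) == 0L) return(0)
  if (length(subset) == length(g)) return(1)
  if (length(g) == 1L) return(1)
  if (lambda == 0) return(sum(g[subset]))
  (prod(1 + lambda * g[subset]) - 1) / lambda
}

# Sugeno integral by exhaustive enumeration of all 2^X - 1 subsets:
# max over subsets A of min(min_{i in A} x_i, g(A))
oracleSugenoIntegral <- function(x, g, lambda) {
  X <- length(x)
  best <- 0
  for (mask in seq_len(2^X - 1)) {
    A <- which(bitwAnd(mask, 2^(seq_len(X) - 1L)) > 0)
    gA <- oracleSubsetMeasure(A, g, lambda)
    best <- max(best, min(min(x[A]), gA))
  }
  best
}

oracleSugenoPredict <- function(dc, g, lambda) {
  N <- dim(dc)[1]; Y <- dim(dc)[3]
  pred <- integer(N)
  for (i in seq_len(N)) {
    fused <- vapply(seq_len(Y), function(y)
      oracleSugenoIntegral(dc[i, , y], g, lambda), numeric(1))
    pred[i] <- which.max(fused)
  }
  pred
}

# random renormalized score tensor
randomScoreTensor <- function(N, X, Y) {
  raw <- array(stats::runif(N * X * Y), dim = c(N, X, Y))
  validateScores(raw, policy = "renormalize")
}
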