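test_that("weighted average reproduces hand arithmetic and degenerate cases", {
  raw <- array(c(1, 0, 0, 1, 0, 0), dim = c(1, 2, 3))
  st <- validateScores(raw)
  res <- weightedAverageFuse(st, classifierWeights(c(2, 1)))
  expect_equal(as.vector(fusedScores(res)), c(2 / 3, 1 / 3, 0))
  expect_identical(predictions(res), 1L)
  expect_identical(res@orientation, "argmax")

  # uniform weights reduce to the arithmetic mean of classifier rows
  set.seed(31)
  st2 <- randomScoreTensor(20, 3, 4)
  uni <- weightedAverageFuse(st2, uniformWeights(3))
  meanRow <- apply(scores(st2), c(1, 3), mean)
  expect_equal(unname(fusedScores(uni)), unname(meanRow), tolerance = 1e-12)
  expect_identical(predictions(uni),
                   as.integer(max.col(meanRow, ties.method = "first")))

  expect_error(classifierWeights(c(0, 0)), "positive")
  expect_error(weightedAverageFuse(st2, classifierWeights(c(1, 1))),
               "one weight per classifier")
})

test_that("weighted average with one classifier returns its own row", {
  set.seed(32)
  st <- randomScoreTensor(5, 1, 3)
  res <- weightedAverageFuse(st)
  expect_equal(unname(fusedScores(res)), unname(classifierMatrix(st, 1)),
               tolerance = 1e-12)
  expect_identical(predictions(res),
                   as.integer(max.col(classifierMatrix(st, 1), "first")))
})

test_that("weighted average matches a loop oracle on random tensors", {
  set.seed(33)
  for (i in 1:100) {
    X <- sample(1:3, 1); Y <- sample(2:4, 1)
    st <- randomScoreTensor(5, X, Y)
    w <- runif(X, 0.1, 1)
    got <- predictions(weightedAverageFuse(st, classifierWeights(w)))
    expect_identical(got, oracleWeightedPredict(scores(st), w))
  }
})

test_that("solveLambda reproduces closed forms and the additive case", {
  expect_identical(solveLambda(c(0.5, 0.5)), 0)
  # X = 2 quadratic: g (1 + lambda g)^2 = 1 + lambda  =>  lambda = (1 - 2g)/g^2
  expect_equal(solveLambda(c(0.9, 0.9)), (1 - 1.8) / 0.81, tolerance = 1e-9)
  expect_equal(solveLambda(c(0.3, 0.3)), (1 - 0.6) / 0.09, tolerance = 1e-9)
  expect_identical(solveLambda(0.7), 0)  # single classifier degenerates
  expect_error(solveLambda(c(0.5, 1.2)), "\\(0, 1\\)")
  expect_error(solveLambda(numeric(0)), "densities")

  # defining identity holds at the returned root
  set.seed(34)
  for (i in 1:30) {
    g <- runif(sample(2:5, 1), 0.05, 0.95)
    lam <- solveLambda(g)
    expect_lt(abs(prod(1 + lam * g) - 1 - lam), 1e-10)
    expect_gt(lam, -1)
  }
})

test_that("the lambda measure is normalized, monotone and matches closed forms", {
  set.seed(35)
  for (i in 1:10) {
    X <- sample(2:5, 1)
    m <- lambdaFuzzyMeasure(runif(X, 0.5, 0.99))
    expect_identical(measureOf(m, integer(0)), 0)
    expect_equal(measureOf(m, seq_len(X)), 1, tolerance = 1e-9)
    # exhaustive subset pairs: A subset of B implies g(A) <= g(B)
    subsets <- lapply(seq_len(2^X - 1), function(mask)
      which(bitwAnd(mask, 2^(seq_len(X) - 1L)) > 0))
    vals <- vapply(subsets, function(A) measureOf(m, A), numeric(1))
    expect_true(all(vals >= 0 & vals <= 1 + 1e-12))
    for (a in seq_along(subsets)) for (b in seq_along(subsets)) {
      if (all(subsets[[a]] %in% subsets[[b]]))
        expect_lte(vals[a], vals[b] + 1e-12)
    }
    # against the independent closed form
    for (a in seq_along(subsets))
      expect_equal(vals[a], oracleSubsetMeasure(subsets[[a]], m@densities,
                                                m@lambda), tolerance = 1e-12)
  }
})

test_that("accuracy rescaling keeps densities strictly inside (0,1)", {
  m <- lambdaFuzzyMeasure(c(0.961, 0.962, 0.963, 0.968))
  expect_true(all(m@densities > 0 & m@densities < 1))
  expect_equal(max(m@densities), 0.968 / 0.968001, tolerance = 1e-9)
  expect_gt(m@lambda, -1)
  expect_equal(measureOf(m, seq_len(4)), 1)
})

test_that("the Sugeno integral is idempotent, internal and matches the subset oracle", {
  set.seed(36)
  # idempotency: identical classifiers reproduce the common row
  row <- c(0.6, 0.3, 0.1)
  raw <- array(0, dim = c(1, 3, 3))
  for (n in 1:3) raw[1, n, ] <- row
  st <- validateScores(raw)
  m <- lambdaFuzzyMeasure(c(0.7, 0.8, 0.9))
  res <- sugenoFuse(st, m)
  expect_equal(as.vector(fusedScores(res)), row, tolerance = 1e-9)
  expect_identical(predictions(res), 1L)

  # X = 1 returns the single classifier's argmax
  one <- randomScoreTensor(5, 1, 3)
  r1 <- sugenoFuse(one, lambdaFuzzyMeasure(0.7))
  expect_identical(predictions(r1),
                   as.integer(max.col(classifierMatrix(one, 1), "first")))

  # exhaustive-subset oracle agreement, and internality
  for (i in 1:100) {
    X <- sample(1:3, 1); Y <- sample(2:4, 1)
    st <- randomScoreTensor(4, X, Y)
    m <- lambdaFuzzyMeasure(runif(X, 0.3, 0.95))
    res <- sugenoFuse(st, m)
    expect_identical(predictions(res),
                     oracleSugenoPredict(scores(st), m@densities, m@lambda))
    lo <- apply(scores(st), c(1, 3), min)
    hi <- apply(scores(st), c(1, 3), max)
    expect_true(all(fusedScores(res) >= lo - 1e-12 &
                    fusedScores(res) <= hi + 1e-12))
  }
})

test_that("both baselines are invariant to joint classifier permutation", {
  set.seed(37)
  st <- randomScoreTensor(30, 4, 3)
  w <- runif(4, 0.5, 1)
  m <- lambdaFuzzyMeasure(w)
  basew <- predictions(weightedAverageFuse(st, classifierWeights(w)))
  bases <- predictions(sugenoFuse(st, m))
  for (i in 1:5) {
    perm <- sample(4)
    stp <- validateScores(scores(st)[, perm, , drop = FALSE])
    expect_identical(
      predictions(weightedAverageFuse(stp, classifierWeights(w[perm]))),
      basew)
    expect_identical(
      predictions(sugenoFuse(stp, lambdaFuzzyMeasure(w[perm]))), bases)
  }
})
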