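test_that("the rank transform hits its printed endpoints and closed form", {
  expect_equal(round(gompertzRank(1), 3), 0.127)
  expect_equal(round(gompertzRank(0), 3), 0.632)
  # direct arithmetic: 1 - exp(-exp(-1))
  expect_equal(gompertzRank(0.5), 0.3077993724, tolerance = 1e-9)
  expect_equal(gompertzRank(0), 1 - exp(-1), tolerance = 1e-15)
  expect_error(gompertzRank(1.2), "\\[0, 1\\]")
  expect_error(gompertzRank(-0.01), "\\[0, 1\\]")
  # general growth-curve helper agrees with the reflected rank form
  expect_equal(1 - gompertzFunction(0.3, a = 1, d = 0, k = 2),
               gompertzRank(0.3), tolerance = 1e-12)
})

test_that("the rank transform is strictly decreasing and bounded on a fine grid", {
  grid <- seq(0, 1, by = 1e-4)
  fr <- gompertzRank(grid)
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr > 0.1265 & fr < 0.6322))
})

test_that("rank positions follow descending confidence with index tie-breaks", {
  p <- gompertzParams(topM = 2)
  st <- validateScores(array(c(0.7, 0.2, 0.1), dim = c(1, 1, 3)))
  frt <- computeFuzzyRanks(st, p)
  expect_identical(as.vector(frt@rankPosition), c(1L, 2L, 3L))
  expect_identical(as.vector(frt@inTopM), c(TRUE, TRUE, FALSE))

  tie <- validateScores(array(rep(1 / 3, 3), dim = c(1, 1, 3)),
                        policy = "renormalize")
  expect_identical(as.vector(computeFuzzyRanks(tie, p)@rankPosition),
                   c(1L, 2L, 3L))

  z <- validateScores(array(c(0, 0.5, 0.5), dim = c(1, 1, 3)))
  frtz <- computeFuzzyRanks(z, p)
  expect_identical(as.vector(frtz@rankPosition), c(3L, 1L, 2L))
  expect_equal(as.vector(frtz@fr), c(1 - exp(-1), 0.3077994, 0.3077994),
               tolerance = 1e-7)
  expect_error(computeFuzzyRanks(z, gompertzParams(topM = 4)), "topM")
})

test_that("fusion reproduces the hand-evaluated two-classifier example", {
  raw <- array(c(0.8, 0.7, 0.15, 0.2, 0.05, 0.1), dim = c(1, 2, 3))
  res <- gompertzFuse(validateScores(raw), gompertzParams(topM = 2))
  b <- res@breakdown
  # class 3 is outside both classifiers' top-2: pure penalty
  expect_equal(b@frSum[1, 3], 2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(b@ccfSum[1, 3], 1)
  # frozen from a scalar evaluation of the defining sums
  expect_equal(b@frSum[1, ], c(0.4013649282, 1.0117314756, 1.2642411177),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(b@ccfSum[1, ], c(0.25, 0.825, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(b@fdc[1, ], c(0.1003412321, 0.8346784674, 1.2642411177),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(predictions(res), 1L)
  expect_identical(res@orientation, "argmin")
})

test_that("a single classifier with full retention reduces to argmax", {
  set.seed(21)
  st <- randomScoreTensor(1000, 1, 4)
  res <- gompertzFuse(st, gompertzParams(topM = 4))
  expected <- max.col(classifierMatrix(st, 1), ties.method = "first")
  expect_identical(predictions(res), as.integer(expected))
})

test_that("unanimous classifiers predict the common argmax", {
  set.seed(22)
  for (i in 1:25) {
    Y <- sample(2:4, 1)
    row <- runif(Y); row <- row / sum(row)
    X <- sample(1:4, 1)
    raw <- array(rep(row, each = 1), dim = c(1, X, Y))
    for (n in seq_len(X)) raw[1, n, ] <- row
    st <- validateScores(raw, policy = "renormalize")
    res <- gompertzFuse(st, gompertzParams(topM = sample(Y, 1)))
    expect_identical(predictions(res), as.integer(which.max(row)))
  }
})

test_that("predictions are invariant to classifier order and equivariant to class relabeling", {
  set.seed(23)
  st <- randomScoreTensor(50, 3, 3)
  p <- gompertzParams(topM = 2)
  base <- predictions(gompertzFuse(st, p))
  for (i in 1:5) {
    perm <- sample(3)
    permuted <- validateScores(scores(st)[, perm, , drop = FALSE])
    expect_identical(predictions(gompertzFuse(permuted, p)), base)
  }
  # class relabeling: avoid ties in dc so tie-break order is immaterial
  for (i in 1:5) {
    cperm <- sample(3)
    relabeled <- validateScores(scores(st)[, , cperm, drop = FALSE])
    pred2 <- predictions(gompertzFuse(relabeled, p))
    expect_identical(cperm[pred2], base)
  }
})

test_that("a fully penalized class never beats a fully retained confident class", {
  set.seed(24)
  penaltyProduct <- NULL
  for (i in 1:20) {
    X <- sample(1:4, 1)
    st <- randomScoreTensor(50, X, 3)
    res <- gompertzFuse(st, gompertzParams(topM = 2))
    frt <- computeFuzzyRanks(st, gompertzParams(topM = 2))
    retainedAll <- apply(frt@inTopM, c(1, 3), all)
    confident <- apply(scores(st) >= 0.05, c(1, 3), all)
    penalizedAll <- apply(!frt@inTopM, c(1, 3), all)
    fdc <- res@breakdown@fdc
    for (s in seq_len(50)) {
      qualifying <- which(retainedAll[s, ] & confident[s, ])
      dead <- which(penalizedAll[s, ])
      # fully penalized classes score exactly X * rank(0) * 1
      for (y in dead)
        expect_equal(fdc[s, y], X * (1 - exp(-1)), tolerance = 1e-12)
      if (length(qualifying) && length(dead)) {
        expect_true(max(fdc[s, qualifying]) < min(fdc[s, dead]))
        expect_false(res@predictions[s] %in% dead)
      }
    }
  }
})

test_that("vectorized fusion matches the loop oracle on random tensors", {
  set.seed(25)
  for (i in 1:300) {
    X <- sample(1:3, 1); Y <- sample(2:4, 1); N <- sample(1:4, 1)
    st <- randomScoreTensor(N, X, Y)
    topM <- sample(Y, 1)
    got <- predictions(gompertzFuse(st, gompertzParams(topM = topM)))
    expect_identical(got, oracleGompertzPredict(scores(st), topM))
  }
})

test_that("the literal uncomplemented confidence sum lets penalized classes win", {
  # documents why the complemented form is the default: under the literal
  # form a fully penalized class has FDC = FRSum * 0 = 0 and wins the argmin
  raw <- array(c(0.8, 0.7, 0.15, 0.2, 0.05, 0.1), dim = c(1, 2, 3))
  st <- validateScores(raw)
  lit <- gompertzFuse(st, gompertzParams(topM = 2, literalCCF = TRUE))
  expect_identical(predictions(lit), 3L)
  expect_equal(lit@breakdown@fdc[1, 3], 0)
  got <- predictions(lit)
  expect_identical(got, oracleGompertzPredict(scores(st), 2, literal = TRUE))
})

test_that("batch fusion equals per-sample fusion and drops the breakdown", {
  set.seed(26)
  st <- randomScoreTensor(100, 3, 3)
  batch <- gompertzFuseBatch(st)
  expect_null(batch@breakdown)
  perSample <- vapply(seq_len(100), function(i) {
    one <- validateScores(scores(st)[i, , , drop = FALSE],
                          policy = "renormalize")
    predictions(gompertzFuse(one))[1]
  }, integer(1))
  expect_identical(batch@predictions, perSample)
  expect_error(validateScores(array(numeric(0), dim = c(0, 2, 3))), "sample")
})
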