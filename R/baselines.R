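#' Construct classifier weights
#'
#' @param weights non-negative numeric weights, one per classifier;
#'   typically validation accuracies.
#' @param source provenance tag: `"validation_accuracy"`,
#'   `"user_supplied"` or `"uniform"`.
#' @return a [ClassifierWeights-class].
#' @export
classifierWeights <- function(weights,
                              source = c("validation_accuracy",
                                         "user_supplied", "uniform")) {
  new("ClassifierWeights", weights = as.numeric(weights),
      source = match.arg(source))
}

#' @describeIn classifierWeights equal weights for `x` classifiers.
#' @param x number of classifiers.
#' @export
uniformWeights <- function(x) {
  classifierWeights(rep(1, x), source = "uniform")
}

#' Weighted-average fusion
#'
#' The fused score of class `y` is the convex combination
#' `sum(w_n * dc_y^n) / sum(w_n)` of the classifier scores; the predicted
#' class maximizes it (ties: lowest class index).
#'
#' @param scores a [ScoreTensor-class].
#' @param weights a [ClassifierWeights-class] or bare numeric vector;
#'   defaults to uniform.
#' @return a [FusionResult-class], orientation `"argmax"`.
#' @export
weightedAverageFuse <- function(scores, weights = NULL) {
  stopifnot(is(scores, "ScoreTensor"))
  X <- nClassifiers(scores)
  if (is.null(weights)) weights <- uniformWeights(X)
  if (is.numeric(weights)) weights <- classifierWeights(weights, "user_supplied")
  w <- weights@weights
  if (length(w) != X)
    stop("need one weight per classifier")
  fused <- apply(sweep(scores@scores, 2, w, `*`), c(1, 3), sum) / sum(w)
  fused <- matrix(fused, nSamples(scores), nClasses(scores))
  dimnames(fused) <- list(scores@sampleIds, scores@classLabels)
  pred <- max.col(fused, ties.method = "first")
  new("FusionResult", fusedScores = fused, predictions = as.integer(pred),
      method = "weighted_average", orientation = "argmax",
      sampleIds = scores@sampleIds, classLabels = scores@classLabels,
      breakdown = NULL)
}

#' Solve for the lambda of a lambda-fuzzy measure
#'
#' Finds the unique `lambda > -1` with
#' `1 + lambda = prod_n (1 + lambda * g_n)`, which normalizes the measure
#' of the full classifier set to 1.  When the densities sum to exactly 1
#' the root is `lambda = 0` (additive measure); when they sum to more
#' (less) than 1 the root is negative (positive).  Root-finding is a
#' bracketed [stats::uniroot()] refined to `|f(lambda)| <= 1e-10`.
#'
#' @param densities fuzzy densities `g_n`, each strictly in `(0, 1)`.
#' @return the scalar lambda.
#' @examples
#' solveLambda(c(0.5, 0.5))   # 0: densities already additive
#' solveLambda(c(0.9, 0.9))   # quadratic root -0.8/0.81
#' @export
solveLambda <- function(densities) {
  g <- as.numeric(densities)
  if (length(g) < 1L || any(!is.finite(g)) || any(g <= 0) || any(g >= 1))
    stop("densities must lie strictly in (0, 1)")
  s <- sum(g)
  if (abs(s - 1) <= 1e-9) return(0)
  if (length(g) == 1L) return(0)  # degenerate: measure normalized directly
  f <- function(lam) prod(1 + lam * g) - 1 - lam
  if (s > 1) {
    # unique root in (-1, 0); f(-1) = prod(1 - g) > 0 always, and with
    # densities close to 1 the root sits within machine epsilon of -1,
    # so the bracket must start at -1 itself
    lo <- -1; hi <- -1e-12
  } else {
    # unique root in (0, Inf): expand the bracket until f changes sign
    lo <- 1e-12; hi <- 1
    while (f(hi) <= 0) hi <- hi * 2
  }
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-15)$root
  # polish by bisection until the defining identity holds to 1e-10
  it <- 0L
  while (abs(f(r)) > 1e-10 && it < 200L) {
    if (sign(f(r)) == sign(f(lo))) lo <- r else hi <- r
    r <- (lo + hi) / 2
    it <- it + 1L
  }
  max(r, -1 + .Machine$double.eps)  # the measure requires lambda > -1
}

#' Build a lambda-fuzzy measure from densities or accuracies
#'
#' Raw per-classifier accuracies `a_n` are rescaled to densities
#' `g_n = a_n / (max(a_n) + 1e-6)` so each lies strictly in `(0, 1)`;
#' already-valid densities can be passed through unscaled.
#'
#' @param accuracies per-classifier accuracies (or densities), positive.
#' @param rescale rescale by the maximum (default `TRUE`); with
#'   `FALSE` the values must already lie in `(0, 1)`.
#' @return a [LambdaFuzzyMeasure-class].
#' @export
lambdaFuzzyMeasure <- function(accuracies, rescale = TRUE) {
  a <- as.numeric(accuracies)
  if (length(a) < 1L || any(!is.finite(a)) || any(a <= 0))
    stop("accuracies must be positive and finite")
  g <- if (rescale) a / (max(a) + 1e-6) else a
  new("LambdaFuzzyMeasure", densities = g, lambda = solveLambda(g))
}

#' @rdname measureOf
#' @export
setMethod("measureOf", "LambdaFuzzyMeasure", function(measure, subset) {
  g <- measure@densities
  X <- length(g)
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > X)) stop("subset indices out of range")
  subset <- unique(subset)
  if (length(subset) == 0L) return(0)
  if (length(subset) == X) return(1)
  if (X == 1L) return(1)  # degenerate single-classifier measure
  lam <- measure@lambda
  if (lam == 0) return(sum(g[subset]))
  (prod(1 + lam * g[subset]) - 1) / lam
})

setMethod("show", "LambdaFuzzyMeasure", function(object) {
  cat(sprintf("LambdaFuzzyMeasure over %d classifiers, lambda = %.6g\n",
              length(object@densities), object@lambda))
  cat("densities:", paste(sprintf("%.4f", object@densities), collapse = ", "),
      "\n")
})

#' Sugeno-integral fusion
#'
#' Per sample and class, the fused score is the Sugeno fuzzy integral of
#' the classifier confidences with respect to the lambda-fuzzy measure:
#' with the scores sorted descending `dc_(1) >= ... >= dc_(X)` and `A_k`
#' the set of the `k` top-scoring classifiers,
#' `S = max_k min(dc_(k), g(A_k))`.  The integral is idempotent and
#' internal (bounded by the min and max classifier score).  The predicted
#' class maximizes `S` (ties: lowest class index).
#'
#' @param scores a [ScoreTensor-class].
#' @param measure a [LambdaFuzzyMeasure-class] over the classifiers, or a
#'   numeric vector of accuracies passed to [lambdaFuzzyMeasure()].
#'   Defaults to equal densities `0.5`.
#' @return a [FusionResult-class], orientation `"argmax"`.
#' @export
sugenoFuse <- function(scores, measure = NULL) {
  stopifnot(is(scores, "ScoreTensor"))
  X <- nClassifiers(scores)
  if (is.null(measure))
    measure <- new("LambdaFuzzyMeasure", densities = rep(0.5, X),
                   lambda = solveLambda(rep(0.5, X)))
  if (is.numeric(measure)) measure <- lambdaFuzzyMeasure(measure)
  if (length(measure@densities) != X)
    stop("measure must cover every classifier")
  g <- measure@densities
  lam <- measure@lambda
  N <- nSamples(scores); Y <- nClasses(scores)
  fused <- matrix(NA_real_, N, Y,
                  dimnames = list(scores@sampleIds, scores@classLabels))
  for (y in seq_len(Y)) {
    m <- matrix(scores@scores[, , y], N, X)
    for (i in seq_len(N)) {
      o <- order(-m[i, ], seq_len(X))
      gA <- 0
      s <- -Inf
      for (k in seq_len(X)) {
        gk <- g[o[k]]
        gA <- if (X == 1L) 1 else gA + gk + lam * gA * gk
        if (k == X) gA <- 1  # measure of the full set is 1 by construction
        s <- max(s, min(m[i, o[k]], gA))
      }
      fused[i, y] <- s
    }
  }
  pred <- max.col(fused, ties.method = "first")
  new("FusionResult", fusedScores = fused, predictions = as.integer(pred),
      method = "sugeno", orientation = "argmax",
      sampleIds = scores@sampleIds, classLabels = scores@classLabels,
      breakdown = NULL)
}
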