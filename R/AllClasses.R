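#' @import methods
NULL

.UNIT_SUM_TOL <- 1e-4  # structural guard at validity; policy tolerance lives in validateScores()

#' ScoreTensor: per-classifier decision scores
#'
#' Container for the decision (confidence) scores of `X` probabilistic
#' classifiers on `N` samples over `Y` classes.  The scores are held as a
#' three-dimensional array indexed `(sample, classifier, class)`; each
#' `(sample, classifier)` row is a probability vector over the classes, as
#' emitted by a softmax output layer.
#'
#' @slot scores numeric array `N x X x Y`; entries in `[0, 1]`, each
#'   `(sample, classifier)` slice summing to 1.
#' @slot sampleIds character vector of length `N`, unique.
#' @slot classifierIds character vector of length `X`, unique.
#' @slot classLabels character vector of length `Y`, unique, in column order.
#'
#' @seealso [validateScores()], [stackClassifierOutputs()]
#' @export
setClass("ScoreTensor",
  representation(
    scores = "array",
    sampleIds = "character",
    classifierIds = "character",
    classLabels = "character"
  )
)

setValidity("ScoreTensor", function(object) {
  d <- dim(object@scores)
  if (length(d) != 3L)
    return("scores must be a 3-d array (sample x classifier x class)")
  if (d[1] < 1L) return("at least one sample required (N >= 1)")
  if (d[2] < 1L) return("at least one classifier required (X >= 1)")
  if (d[3] < 2L) return("at least two classes required (Y >= 2)")
  if (length(object@sampleIds) != d[1])
    return("sampleIds length does not match sample dimension")
  if (length(object@classifierIds) != d[2])
    return("classifierIds length does not match classifier dimension")
  if (length(object@classLabels) != d[3])
    return("classLabels length does not match class dimension")
  if (anyDuplicated(object@sampleIds)) return("duplicate sample ids")
  if (anyDuplicated(object@classifierIds)) return("duplicate classifier ids")
  if (anyDuplicated(object@classLabels)) return("duplicate class labels")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  if (any(object@scores < 0) || any(object@scores > 1))
    return("scores must lie in [0, 1]")
  rs <- apply(object@scores, c(1, 2), sum)
  if (any(abs(rs - 1) > .UNIT_SUM_TOL))
    return("each (sample, classifier) row must sum to 1")
  TRUE
})

#' LabelVector: ground-truth class labels
#'
#' Integer class index per sample (1-based, pointing into `classLabels`),
#' together with the ordered class vocabulary.
#'
#' @slot labels integer vector, each in `1..Y`.
#' @slot classLabels ordered class names.
#' @export
setClass("LabelVector",
  representation(labels = "integer", classLabels = "character")
)

setValidity("LabelVector", function(object) {
  Y <- length(object@classLabels)
  if (Y < 2L) return("at least two class labels required")
  if (anyDuplicated(object@classLabels)) return("duplicate class labels")
  if (length(object@labels) < 1L) return("empty label vector")
  if (any(is.na(object@labels))) return("labels must not contain NA")
  if (any(object@labels < 1L | object@labels > Y))
    return("labels must be class indices in 1..Y")
  TRUE
})

#' GompertzParams: parameters of the fuzzy-rank fusion
#'
#' The rank transform is the re-parameterized Gompertz curve
#' `a * exp(-exp(d - k * dc))` reflected to `1 - exp(-exp(-k * dc))` with
#' `a = 1`, `d = 0`, `k = 2`, mapping a confidence score `dc` in `[0, 1]`
#' to a fuzzy rank in `(~0.1266, ~0.6321]` (lower = more confident).
#'
#' @slot a asymptote of the Gompertz curve (fixed 1).
#' @slot d x-axis displacement (fixed 0).
#' @slot k y-scaling (fixed 2).
#' @slot topM number of most-confident classes retained per classifier;
#'   classes ranked below receive the penalty contributions.
#' @slot penaltyFR fuzzy-rank penalty, the rank of a zero-confidence score:
#'   `1 - exp(-1)` (prints as 0.632).
#' @slot penaltyDC confidence contribution of a penalized class (0).
#' @slot literalCCF if `TRUE`, use the uncomplemented confidence-factor sum
#'   `CCFSum = (1/X) * sum(contrib)`; the default `FALSE` uses the
#'   complement `1 - (1/X) * sum(contrib)`, which is what makes the
#'   penalties actually prevent a class from winning the argmin.
#' @export
setClass("GompertzParams",
  representation(
    a = "numeric", d = "numeric", k = "numeric",
    topM = "integer",
    penaltyFR = "numeric", penaltyDC = "numeric",
    literalCCF = "logical"
  )
)

setValidity("GompertzParams", function(object) {
  for (s in c("a", "d", "k", "penaltyFR", "penaltyDC"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("%s must be a finite scalar", s))
  if (length(object@topM) != 1L || is.na(object@topM) || object@topM < 1L)
    return("topM must be a positive integer")
  # the FR penalty is by construction the rank of a zero-confidence score
  zeroRank <- object@a * (1 - exp(-exp(object@d)))
  if (abs(object@penaltyFR - zeroRank) > 5e-4)
    return("penaltyFR must equal the rank function at zero confidence")
  if (length(object@literalCCF) != 1L || is.na(object@literalCCF))
    return("literalCCF must be TRUE or FALSE")
  TRUE
})

#' FuzzyRankTensor: Gompertz fuzzy ranks with top-m membership
#'
#' @slot fr numeric array `N x X x Y` of fuzzy ranks.
#' @slot rankPosition integer array of the same shape; within each
#'   `(sample, classifier)` row a permutation of `1..Y`, 1 = most confident,
#'   ties in confidence broken by ascending class index.
#' @slot inTopM logical array, `rankPosition <= topM`.
#' @slot topM the retained-set size used.
#' @export
setClass("FuzzyRankTensor",
  representation(
    fr = "array", rankPosition = "array", inTopM = "array", topM = "integer"
  )
)

setValidity("FuzzyRankTensor", function(object) {
  d <- dim(object@fr)
  if (!identical(d, dim(object@rankPosition)) || !identical(d, dim(object@inTopM)))
    return("fr, rankPosition and inTopM must share dimensions")
  if (!identical(object@inTopM, object@rankPosition <= object@topM))
    return("inTopM must equal rankPosition <= topM")
  TRUE
})

#' FusionBreakdown: intermediate quantities of the fuzzy-rank fusion
#'
#' @slot frSum sample-by-class fuzzy-rank sums (penalty-substituted).
#' @slot ccfSum sample-by-class complement-of-confidence-factor sums.
#' @slot fdc fused decision scores, `frSum * ccfSum`; the predicted class
#'   minimizes this.
#' @export
setClass("FusionBreakdown",
  representation(frSum = "matrix", ccfSum = "matrix", fdc = "matrix")
)

setValidity("FusionBreakdown", function(object) {
  if (!identical(dim(object@frSum), dim(object@ccfSum)) ||
      !identical(dim(object@frSum), dim(object@fdc)))
    return("frSum, ccfSum and fdc must share dimensions")
  if (max(abs(object@fdc - object@frSum * object@ccfSum)) > 1e-12)
    return("fdc must equal frSum * ccfSum")
  TRUE
})

#' FusionResult: fused scores and predictions of one ensemble method
#'
#' @slot fusedScores sample-by-class matrix of fused decision scores.
#' @slot predictions integer class index per sample (1-based).
#' @slot method one of `"gompertz"`, `"weighted_average"`, `"sugeno"`,
#'   or `"single"` for a lone base classifier.
#' @slot orientation `"argmin"` (gompertz: lowest fused score wins) or
#'   `"argmax"` (the others).
#' @slot sampleIds,classLabels carried over from the input tensor.
#' @slot breakdown a [FusionBreakdown-class] for the gompertz method,
#'   otherwise `NULL`.
#' @export
setClass("FusionResult",
  representation(
    fusedScores = "matrix",
    predictions = "integer",
    method = "character",
    orientation = "character",
    sampleIds = "character",
    classLabels = "character",
    breakdown = "ANY"
  )
)

setValidity("FusionResult", function(object) {
  N <- nrow(object@fusedScores)
  Y <- ncol(object@fusedScores)
  if (length(object@predictions) != N)
    return("one prediction per sample required")
  if (any(object@predictions < 1L | object@predictions > Y))
    return("predictions must be class indices in 1..Y")
  if (!object@orientation %in% c("argmin", "argmax"))
    return("orientation must be 'argmin' or 'argmax'")
  if (!object@method %in% c("gompertz", "weighted_average", "sugeno", "single"))
    return("unknown method")
  if (length(object@sampleIds) != N || length(object@classLabels) != Y)
    return("id lengths must match fusedScores dimensions")
  pick <- if (object@orientation == "argmin") {
    max.col(-object@fusedScores, ties.method = "first")
  } else {
    max.col(object@fusedScores, ties.method = "first")
  }
  if (!identical(as.integer(pick), object@predictions))
    return("predictions inconsistent with fusedScores under the stated orientation")
  TRUE
})

#' ClassifierWeights: weights for weighted-average fusion
#'
#' @slot weights non-negative weight per classifier, at least one positive.
#'   Typically the per-classifier validation accuracies.
#' @slot source one of `"validation_accuracy"`, `"user_supplied"`, `"uniform"`.
#' @export
setClass("ClassifierWeights",
  representation(weights = "numeric", source = "character")
)

setValidity("ClassifierWeights", function(object) {
  if (length(object@weights) < 1L) return("at least one weight required")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    return("weights must be finite and non-negative")
  if (sum(object@weights) <= 0) return("at least one weight must be positive")
  if (!object@source %in% c("validation_accuracy", "user_supplied", "uniform"))
    return("unknown weight source")
  TRUE
})

#' LambdaFuzzyMeasure: a Sugeno lambda-fuzzy measure over classifiers
#'
#' Built from per-classifier densities `g_n` in `(0, 1)`; `lambda > -1`
#' solves `1 + lambda = prod(1 + lambda * g_n)` so that the full classifier
#' set has measure 1.  Subset measures follow the recursion
#' `g(A + {i}) = g(A) + g_i + lambda * g(A) * g_i`.
#'
#' @slot densities fuzzy density per classifier, each in `(0, 1)`.
#' @slot lambda the normalizing root (`0` when the densities sum to 1; for a
#'   single classifier the measure degenerates to `g({1}) = 1`).
#' @export
setClass("LambdaFuzzyMeasure",
  representation(densities = "numeric", lambda = "numeric")
)

setValidity("LambdaFuzzyMeasure", function(object) {
  g <- object@densities
  if (length(g) < 1L) return("at least one density required")
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1))
    return("densities must lie strictly in (0, 1)")
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda <= -1)
    return("lambda must be a finite scalar > -1")
  TRUE
})

#' EvaluationReport: confusion matrix and per-class metrics
#'
#' One-vs-rest reduction of a multi-class confusion matrix: per class,
#' precision `TP/(TP+FP)`, recall (sensitivity) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and F1 `2PR/(P+R)`; overall accuracy is the fraction of
#' correct predictions.  Zero denominators yield 0 (with a warning at
#' computation time).
#'
#' @slot confusion integer matrix, true class in rows, predicted in columns.
#' @slot perClass data.frame with columns class, precision, recall,
#'   specificity, f1.
#' @slot accuracy overall fraction correct.
#' @slot macro named numeric vector: unweighted means of the per-class
#'   metrics.
#' @export
setClass("EvaluationReport",
  representation(
    confusion = "matrix", perClass = "data.frame",
    accuracy = "numeric", macro = "numeric"
  )
)

setValidity("EvaluationReport", function(object) {
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
  if (any(cm < 0)) return("confusion entries must be non-negative")
  n <- sum(cm)
  if (n < 1) return("confusion matrix must count at least one sample")
  if (abs(object@accuracy - sum(diag(cm)) / n) > 1e-12)
    return("accuracy must equal trace(confusion) / N")
  needed <- c("class", "precision", "recall", "specificity", "f1")
  if (!all(needed %in% names(object@perClass)))
    return("perClass must have class, precision, recall, specificity, f1")
  m <- as.matrix(object@perClass[, needed[-1]])
  if (any(m < 0 | m > 1)) return("per-class metrics must lie in [0, 1]")
  TRUE
})

#' SyntheticConfig: parameters of the synthetic score generator
#'
#' @slot nSamples number of test samples `N`.
#' @slot nClassifiers number of emulated classifiers `X`.
#' @slot nClasses number of classes `Y`.
#' @slot targetAccuracies per-classifier probability that the Dirichlet peak
#'   is placed on the true class; each in `(1/Y, 1]`.
#' @slot concentrationBase Dirichlet concentration of non-peak classes.
#' @slot concentrationPeak Dirichlet concentration of the peak class.
#' @slot correlation probability that a classifier copies a shared latent
#'   peak draw instead of drawing independently (0 = independent errors).
#' @slot seed integer RNG seed; the generator is fully reproducible from it.
#' @export
setClass("SyntheticConfig",
  representation(
    nSamples = "integer", nClassifiers = "integer", nClasses = "integer",
    targetAccuracies = "numeric",
    concentrationBase = "numeric", concentrationPeak = "numeric",
    correlation = "numeric", seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (object@nClassifiers < 1L) return("nClassifiers must be >= 1")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (length(object@targetAccuracies) != object@nClassifiers)
    return("one target accuracy per classifier required")
  Y <- object@nClasses
  if (any(object@targetAccuracies <= 1 / Y) || any(object@targetAccuracies > 1))
    return("target accuracies must lie in (1/Y, 1]")
  if (object@concentrationBase <= 0)
    return("concentrationBase must be positive")
  if (object@concentrationPeak <= object@concentrationBase)
    return("concentrationPeak must exceed concentrationBase")
  if (object@correlation < 0 || object@correlation > 1)
    return("correlation must lie in [0, 1]")
  if (is.na(object@seed)) return("seed must be an integer")
  TRUE
})
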