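#' The Gompertz growth curve
#'
#' `a * exp(-exp(d - k * t))`: a double-exponential sigmoid rising from 0
#' to the asymptote `a`, originally a mortality model and widely used for
#' tumour and population growth.  Exposed for transparency; the fusion
#' itself uses the re-parameterized decreasing form [gompertzRank()].
#'
#' @param t independent variable.
#' @param a asymptote.
#' @param d x-axis displacement.
#' @param k y-scaling rate.
#' @return `a * exp(-exp(d - k * t))`, vectorized over `t`.
#' @export
gompertzFunction <- function(t, a = 1, d = 0, k = 2) {
  a * exp(-exp(d - k * t))
}

#' Fuzzy rank of a confidence score
#'
#' Maps a softmax confidence score `dc` in `[0, 1]` to the fuzzy rank
#' `1 - exp(-exp(-2 * dc))`, the re-parameterized (reflected) Gompertz
#' curve.  The map is strictly decreasing: full confidence (`dc = 1`)
#' gives the lowest rank value `1 - exp(-exp(-2))` (prints as 0.127),
#' zero confidence gives `1 - exp(-1)` (prints as 0.632), which doubles
#' as the rank penalty for classes outside the retained top-m set.
#'
#' @param dc numeric vector of confidence scores in `[0, 1]`.
#' @param params a [GompertzParams-class]; only the curve constants
#'   `a`, `d`, `k` are used.
#' @return fuzzy ranks, same shape as `dc`.
#' @examples
#' round(gompertzRank(c(0, 0.5, 1)), 3)
#' @export
gompertzRank <- function(dc, params = gompertzParams()) {
  if (any(!is.finite(dc)) || any(dc < 0) || any(dc > 1))
    stop("confidence scores must lie in [0, 1]")
  params@a * (1 - exp(-exp(params@d - params@k * dc)))
}

#' Construct fusion parameters
#'
#' @param topM number of most-confident classes each classifier retains;
#'   must satisfy `1 <= topM <= Y` at fusion time.  The default 2 retains
#'   the two strongest classes of a three-class problem and penalizes the
#'   weakest.
#' @param literalCCF use the uncomplemented confidence-factor sum (see
#'   [GompertzParams-class]); default `FALSE`.
#' @param a,d,k Gompertz curve constants; fixed to the re-parameterized
#'   form (1, 0, 2) and not normally changed.
#' @return a [GompertzParams-class].
#' @export
gompertzParams <- function(topM = 2L, literalCCF = FALSE,
                           a = 1, d = 0, k = 2) {
  penaltyFR <- a * (1 - exp(-exp(d)))  # rank of a zero-confidence score
  new("GompertzParams", a = a, d = d, k = k, topM = as.integer(topM),
      penaltyFR = penaltyFR, penaltyDC = 0, literalCCF = literalCCF)
}

# rank positions within each row of a matrix: 1 = largest value, ties
# broken by ascending column index
.rankDescending <- function(m) {
  t(apply(m, 1L, function(r) {
    o <- order(-r, seq_along(r))
    rp <- integer(length(r))
    rp[o] <- seq_along(r)
    rp
  }))
}

#' Compute fuzzy ranks and top-m membership
#'
#' Applies [gompertzRank()] elementwise and, within each
#' `(sample, classifier)` row, assigns rank positions 1..Y by descending
#' confidence (equivalently ascending fuzzy rank), ties broken by
#' ascending class index.  A class is in the retained set when its rank
#' position is at most `topM`.
#'
#' @param scores a [ScoreTensor-class].
#' @param params a [GompertzParams-class].
#' @return a [FuzzyRankTensor-class].
#' @export
computeFuzzyRanks <- function(scores, params = gompertzParams()) {
  stopifnot(is(scores, "ScoreTensor"), is(params, "GompertzParams"))
  Y <- nClasses(scores)
  if (params@topM > Y)
    stop("topM must not exceed the number of classes")
  dc <- scores@scores
  d <- dim(dc)
  fr <- array(gompertzRank(as.vector(dc), params), dim = d)
  flat <- matrix(dc, nrow = d[1] * d[2], ncol = d[3])  # rows = (sample, classifier)
  rp <- array(.rankDescending(flat), dim = d)
  new("FuzzyRankTensor", fr = fr, rankPosition = rp,
      inTopM = rp <= params@topM, topM = params@topM)
}

#' Fuse classifier scores by Gompertz fuzzy ranks
#'
#' For each sample and class `y`, sums the fuzzy ranks over classifiers,
#' substituting the penalty rank `1 - exp(-1)` whenever the class falls
#' outside a classifier's top-m set; the confidence-factor sum likewise
#' substitutes a zero contribution for penalized classes.  The fused
#' decision score is
#' `FDC_y = FRSum_y * CCFSum_y` with
#' `CCFSum_y = 1 - mean(retained confidences)` (or, with
#' `literalCCF = TRUE`, the uncomplemented mean itself), and the predicted
#' class minimizes `FDC`, ties broken by lowest class index.
#'
#' @param scores a [ScoreTensor-class].
#' @param params a [GompertzParams-class].
#' @return a [FusionResult-class] (orientation `"argmin"`) carrying a
#'   [FusionBreakdown-class] in its `breakdown` slot.
#' @examples
#' raw <- array(c(0.8, 0.7, 0.15, 0.2, 0.05, 0.1), dim = c(1, 2, 3))
#' res <- gompertzFuse(validateScores(raw), gompertzParams(topM = 2))
#' predictions(res)
#' @export
gompertzFuse <- function(scores, params = gompertzParams()) {
  stopifnot(is(scores, "ScoreTensor"))
  frt <- computeFuzzyRanks(scores, params)
  N <- nSamples(scores); X <- nClassifiers(scores); Y <- nClasses(scores)
  dc <- scores@scores
  frContrib <- ifelse(frt@inTopM, frt@fr, params@penaltyFR)
  dcContrib <- ifelse(frt@inTopM, dc, params@penaltyDC)
  frSum <- apply(frContrib, c(1, 3), sum)
  confMean <- apply(dcContrib, c(1, 3), sum) / X
  ccfSum <- if (params@literalCCF) confMean else 1 - confMean
  frSum <- matrix(frSum, N, Y); ccfSum <- matrix(ccfSum, N, Y)
  fdc <- frSum * ccfSum
  dimnames(fdc) <- list(scores@sampleIds, scores@classLabels)
  pred <- max.col(-fdc, ties.method = "first")
  breakdown <- new("FusionBreakdown", frSum = frSum, ccfSum = ccfSum,
                   fdc = fdc)
  new("FusionResult", fusedScores = fdc, predictions = as.integer(pred),
      method = "gompertz", orientation = "argmin",
      sampleIds = scores@sampleIds, classLabels = scores@classLabels,
      breakdown = breakdown)
}

#' @describeIn gompertzFuse batch alias: identical predictions, breakdown
#'   dropped.
#' @export
gompertzFuseBatch <- function(scores, params = gompertzParams()) {
  res <- gompertzFuse(scores, params)
  res@breakdown <- NULL
  res
}

#' @rdname FusionResult-class
#' @export
setMethod("predictions", "FusionResult", function(object) object@predictions)

#' @rdname FusionResult-class
#' @export
setMethod("fusedScores", "FusionResult", function(object) object@fusedScores)

#' @rdname FusionResult-class
#' @export
setMethod("predictedLabels", "FusionResult", function(object)
  object@classLabels[object@predictions])

#' @rdname FusionResult-class
#' @export
setMethod("sampleIds", "FusionResult", function(object) object@sampleIds)

#' @rdname FusionResult-class
#' @export
setMethod("classLabels", "FusionResult", function(object) object@classLabels)

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult (%s, winner = %s): %d samples, %d classes\n",
              object@method, object@orientation,
              length(object@predictions), length(object@classLabels)))
  tab <- table(factor(object@classLabels[object@predictions],
                      levels = object@classLabels))
  print(tab)
})
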