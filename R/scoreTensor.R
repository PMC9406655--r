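#' Validate a raw score tensor into a ScoreTensor
#'
#' Checks that every `(sample, classifier)` row of decision scores is a
#' probability vector.  Under `policy = "strict"` a row whose sum deviates
#' from 1 by more than `tol` is an error; under `policy = "renormalize"`
#' rows are divided by their sums.  Negative or non-finite entries are
#' always an error, as is a zero-sum row under renormalization.
#'
#' @param raw numeric array `N x X x Y` (sample, classifier, class), or an
#'   `N x Y` matrix for a single classifier.
#' @param policy `"strict"` or `"renormalize"`.
#' @param tol unit-sum tolerance for the strict policy.  The default 1e-6
#'   admits single-precision softmax output.
#' @param sampleIds,classifierIds,classLabels optional identifiers; defaults
#'   are generated (`s1..sN`, `clf1..clfX`, `class1..classY`).
#' @return a validated [ScoreTensor-class].
#' @examples
#' raw <- array(c(0.5, 0.3, 0.2), dim = c(1, 1, 3))
#' st <- validateScores(raw)
#' scores(st)
#' @export
validateScores <- function(raw, policy = c("strict", "renormalize"),
                           tol = 1e-6,
                           sampleIds = NULL, classifierIds = NULL,
                           classLabels = NULL) {
  policy <- match.arg(policy)
  if (is.matrix(raw)) raw <- array(raw, dim = c(nrow(raw), 1L, ncol(raw)))
  if (!is.array(raw) || length(dim(raw)) != 3L)
    stop("raw scores must be a 3-d array (sample x classifier x class) ",
         "or a sample x class matrix")
  if (any(!is.finite(raw))) stop("scores must be finite")
  if (any(raw < 0)) stop("scores must be non-negative")
  d <- dim(raw)
  rs <- apply(raw, c(1, 2), sum)
  if (policy == "strict") {
    # tiny additive slack so a deviation of exactly tol (up to rounding of
    # the sum itself) counts as inside the tolerance
    bad <- which(abs(rs - 1) > tol + 64 * .Machine$double.eps, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf(
        "row (sample %d, classifier %d) sums to %.8g, deviating from 1 by more than %g",
        bad[1, 1], bad[1, 2], rs[bad[1, 1], bad[1, 2]], tol))
  } else {
    if (any(rs == 0)) stop("cannot renormalize a zero-sum score row")
    raw <- sweep(raw, c(1, 2), rs, "/")
  }
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(d[1]))
  if (is.null(classifierIds)) classifierIds <- paste0("clf", seq_len(d[2]))
  if (is.null(classLabels)) classLabels <- paste0("class", seq_len(d[3]))
  new("ScoreTensor",
      scores = raw,
      sampleIds = as.character(sampleIds),
      classifierIds = as.character(classifierIds),
      classLabels = as.character(classLabels))
}

#' Stack per-classifier score matrices into one tensor
#'
#' @param matrices list of `N x Y` numeric matrices, one per classifier,
#'   with identical sample order.  If the matrices carry rownames they must
#'   agree exactly (no silent reordering).
#' @param classifierIds identifiers for the classifiers; defaults to the
#'   list names or `clf1..clfX`.
#' @param policy,tol forwarded to [validateScores()].
#' @inheritParams validateScores
#' @return a [ScoreTensor-class] with the classifier axis in list order.
#' @export
stackClassifierOutputs <- function(matrices, classifierIds = NULL,
                                   sampleIds = NULL, classLabels = NULL,
                                   policy = "strict", tol = 1e-6) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need a non-empty list of score matrices")
  d1 <- dim(matrices[[1]])
  for (m in matrices) {
    if (!is.matrix(m) || !identical(dim(m), d1))
      stop("all classifier matrices must share the same sample x class shape")
    if (!identical(rownames(m), rownames(matrices[[1]])))
      stop("sample ids (rownames) differ across classifier matrices")
    if (!identical(colnames(m), colnames(matrices[[1]])))
      stop("class labels (colnames) differ across classifier matrices")
  }
  X <- length(matrices)
  raw <- array(NA_real_, dim = c(d1[1], X, d1[2]))
  for (n in seq_len(X)) raw[, n, ] <- matrices[[n]]
  if (is.null(classifierIds))
    classifierIds <- if (!is.null(names(matrices))) names(matrices)
                     else paste0("clf", seq_len(X))
  if (is.null(sampleIds)) sampleIds <- rownames(matrices[[1]])
  if (is.null(classLabels)) classLabels <- colnames(matrices[[1]])
  validateScores(raw, policy = policy, tol = tol,
                 sampleIds = sampleIds, classifierIds = classifierIds,
                 classLabels = classLabels)
}

#' Extract one classifier's sample-by-class score matrix
#'
#' @param object a [ScoreTensor-class].
#' @param classifier classifier index or id.
#' @return an `N x Y` matrix with sample ids as rownames and class labels
#'   as colnames.
#' @export
classifierMatrix <- function(object, classifier) {
  stopifnot(is(object, "ScoreTensor"))
  if (is.character(classifier))
    classifier <- match(classifier, object@classifierIds)
  if (is.na(classifier) || classifier < 1 ||
      classifier > length(object@classifierIds))
    stop("unknown classifier")
  m <- object@scores[, classifier, , drop = FALSE]
  m <- array(m, dim = dim(m)[c(1, 3)])
  dimnames(m) <- list(object@sampleIds, object@classLabels)
  m
}

#' Construct a LabelVector
#'
#' @param labels class labels, either as character values drawn from
#'   `classLabels` or as 1-based integer indices.
#' @param classLabels ordered class vocabulary.
#' @return a [LabelVector-class].
#' @export
labelVector <- function(labels, classLabels) {
  if (is.character(labels) || is.factor(labels)) {
    idx <- match(as.character(labels), classLabels)
    if (any(is.na(idx)))
      stop("label value(s) outside the class vocabulary: ",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
    labels <- idx
  }
  new("LabelVector", labels = as.integer(labels),
      classLabels = as.character(classLabels))
}

#' @rdname ScoreTensor-class
#' @export
setMethod("scores", "ScoreTensor", function(object) object@scores)

#' @rdname ScoreTensor-class
#' @export
setMethod("sampleIds", "ScoreTensor", function(object) object@sampleIds)

#' @rdname ScoreTensor-class
#' @export
setMethod("classifierIds", "ScoreTensor", function(object) object@classifierIds)

#' @rdname ScoreTensor-class
#' @export
setMethod("classLabels", "ScoreTensor", function(object) object@classLabels)

#' @rdname ScoreTensor-class
#' @export
setMethod("nSamples", "ScoreTensor", function(object) dim(object@scores)[1])

#' @rdname ScoreTensor-class
#' @export
setMethod("nClassifiers", "ScoreTensor", function(object) dim(object@scores)[2])

#' @rdname ScoreTensor-class
#' @export
setMethod("nClasses", "ScoreTensor", function(object) dim(object@scores)[3])

setMethod("show", "ScoreTensor", function(object) {
  cat(sprintf("ScoreTensor: %d samples x %d classifiers x %d classes\n",
              nSamples(object), nClassifiers(object), nClasses(object)))
  cat("classifiers:", paste(object@classifierIds, collapse = ", "), "\n")
  cat("classes:    ", paste(object@classLabels, collapse = ", "), "\n")
})

#' @rdname LabelVector-class
#' @param object a LabelVector.
#' @export
setMethod("classLabels", "LabelVector", function(object) object@classLabels)

#' @rdname LabelVector-class
#' @export
setMethod("nSamples", "LabelVector", function(object) length(object@labels))

#' Integer class indices of a LabelVector
#' @param object a [LabelVector-class].
#' @return 1-based integer vector.
#' @export
classIndices <- function(object) {
  stopifnot(is(object, "LabelVector"))
  object@labels
}

setMethod("show", "LabelVector", function(object) {
  tab <- table(factor(object@classLabels[object@labels],
                      levels = object@classLabels))
  cat(sprintf("LabelVector: %d samples, %d classes\n",
              length(object@labels), length(object@classLabels)))
  print(tab)
})
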