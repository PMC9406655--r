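#' Confusion matrix and per-class evaluation metrics
#'
#' Tallies the confusion matrix (true class in rows, predicted class in
#' columns) and derives, per class in a one-vs-rest reduction:
#' precision `TP/(TP+FP)`, recall (sensitivity) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and `F1 = 2PR/(P+R)`; plus overall accuracy
#' `trace(confusion)/N` and the unweighted (macro) means.  A metric with
#' a zero denominator is reported as 0 with a warning, so batch tables
#' stay total.
#'
#' @param predictions a [FusionResult-class], a [LabelVector-class], or a
#'   bare integer vector of 1-based class indices.
#' @param truth a [LabelVector-class] or a bare integer vector; with bare
#'   vectors `classLabels` supplies the vocabulary.
#' @param classLabels ordered class names; required only when neither
#'   argument carries them.
#' @return an [EvaluationReport-class].
#' @examples
#' truth <- labelVector(c(1, 1, 2, 2, 3, 3), c("normal", "benign", "malignant"))
#' rep <- evaluatePredictions(c(1L, 2L, 2L, 2L, 3L, 1L), truth)
#' accuracy(rep)
#' @export
evaluatePredictions <- function(predictions, truth, classLabels = NULL) {
  if (is(predictions, "FusionResult")) {
    if (is.null(classLabels)) classLabels <- predictions@classLabels
    predictions <- predictions@predictions
  } else if (is(predictions, "LabelVector")) {
    if (is.null(classLabels)) classLabels <- predictions@classLabels
    predictions <- predictions@labels
  }
  if (is(truth, "LabelVector")) {
    if (is.null(classLabels)) classLabels <- truth@classLabels
    truth <- truth@labels
  }
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  if (length(predictions) == 0L) stop("empty input")
  if (length(predictions) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truth labels",
                 length(predictions), length(truth)))
  if (is.null(classLabels))
    classLabels <- paste0("class", seq_len(max(truth, predictions)))
  Y <- length(classLabels)
  if (any(truth < 1L | truth > Y) || any(predictions < 1L | predictions > Y))
    stop("class indices outside 1..Y")
  lv <- seq_len(Y)
  cm <- table(factor(truth, levels = lv), factor(predictions, levels = lv))
  cm <- matrix(as.integer(cm), Y, Y, dimnames = list(classLabels, classLabels))
  N <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- N - tp - fp - fn
  safeDiv <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning(sprintf("%s undefined (zero denominator) for class(es) %s; reported as 0",
                      what, paste(classLabels[den == 0], collapse = ", ")),
              call. = FALSE)
    out
  }
  precision <- safeDiv(tp, tp + fp, "precision")
  recall <- safeDiv(tp, tp + fn, "recall")
  specificity <- safeDiv(tn, tn + fp, "specificity")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  perClass <- data.frame(
    class = classLabels, precision = as.numeric(precision),
    recall = as.numeric(recall), specificity = as.numeric(specificity),
    f1 = as.numeric(f1), row.names = NULL, stringsAsFactors = FALSE)
  macro <- c(precision = mean(precision), recall = mean(recall),
             specificity = mean(specificity), f1 = mean(f1))
  new("EvaluationReport", confusion = cm, perClass = perClass,
      accuracy = sum(tp) / N, macro = macro)
}

#' @rdname EvaluationReport-class
#' @param object an EvaluationReport.
#' @export
confusionMatrix <- function(object) {
  stopifnot(is(object, "EvaluationReport"))
  object@confusion
}

#' @rdname EvaluationReport-class
#' @export
accuracy <- function(object) {
  stopifnot(is(object, "EvaluationReport"))
  object@accuracy
}

#' @rdname EvaluationReport-class
#' @export
perClassMetrics <- function(object) {
  stopifnot(is(object, "EvaluationReport"))
  object@perClass
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d samples, accuracy %.2f%%\n",
              sum(object@confusion), 100 * object@accuracy))
  cat("confusion (true x predicted):\n")
  print(object@confusion)
  pc <- object@perClass
  pc[-1] <- lapply(pc[-1], round, 3)
  print(pc, row.names = FALSE)
})

#' Comparison table across fusion methods
#'
#' Flattens a set of evaluation reports into the long per-class layout
#' Model, Class, Precision, Recall, Specificity, F1, Accuracy (accuracy
#' in percent, repeated along each model's class rows).  Full precision
#' is kept; rounding (3 decimals for metrics, 2 for accuracy percent) is
#' applied only by `print`/CSV consumers that request it.
#'
#' @param reports named list of [EvaluationReport-class] objects; names
#'   are the model/method identifiers.
#' @return a data.frame, one row per (model, class).
#' @export
reportTable <- function(reports) {
  if (!is.list(reports) || length(reports) == 0L)
    stop("need a non-empty named list of EvaluationReport objects")
  if (is.null(names(reports)) || any(!nzchar(names(reports))))
    stop("reports must be named by model")
  ref <- rownames(reports[[1]]@confusion)
  rows <- lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    if (!is(rep, "EvaluationReport")) stop("all entries must be EvaluationReport")
    if (!identical(rownames(rep@confusion), ref))
      stop("inconsistent class sets across reports")
    pc <- rep@perClass
    data.frame(Model = nm, Class = pc$class, Precision = pc$precision,
               Recall = pc$recall, Specificity = pc$specificity,
               F1 = pc$f1, Accuracy = 100 * rep@accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a comparison table for display
#'
#' @param tab a data.frame from [reportTable()].
#' @return the table with metrics rounded to 3 decimals and accuracy to 2.
#' @export
formatReportTable <- function(tab) {
  for (col in c("Precision", "Recall", "Specificity", "F1"))
    tab[[col]] <- round(tab[[col]], 3)
  tab$Accuracy <- round(tab$Accuracy, 2)
  tab
}
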