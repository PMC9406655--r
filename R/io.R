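#' Read per-classifier score files into a ScoreTensor
#'
#' Each CSV carries one classifier's scores: a `sample_id` column followed
#' by one numeric column per class; sample order and class headers must be
#' identical across files (no silent reordering).
#'
#' @param paths character vector of CSV paths, one per classifier; names,
#'   if present, become the classifier ids (default: file basenames
#'   without extension).
#' @param policy,tol forwarded to [validateScores()].
#' @return a [ScoreTensor-class].
#' @export
readScoresCsv <- function(paths, policy = "strict", tol = 1e-6) {
  if (length(paths) < 1L) stop("need at least one score file")
  readOne <- function(p) {
    df <- utils::read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "sample_id")
      stop(sprintf("%s: first column must be 'sample_id'", p))
    if (ncol(df) < 3L)
      stop(sprintf("%s: need at least two class columns", p))
    if (anyDuplicated(df$sample_id))
      stop(sprintf("%s: duplicate sample ids", p))
    num <- df[-1]
    bad <- !vapply(num, is.numeric, logical(1))
    if (any(bad))
      stop(sprintf("%s: non-numeric cells in column(s) %s", p,
                   paste(names(num)[bad], collapse = ", ")))
    m <- as.matrix(num)
    rownames(m) <- as.character(df$sample_id)
    m
  }
  mats <- lapply(paths, readOne)
  ref <- mats[[1]]
  for (i in seq_along(mats)[-1]) {
    if (!identical(colnames(mats[[i]]), colnames(ref)))
      stop(sprintf("%s: class headers differ from %s", paths[i], paths[1]))
    if (!identical(rownames(mats[[i]]), rownames(ref)))
      stop(sprintf("%s: sample ids differ from %s", paths[i], paths[1]))
  }
  ids <- if (!is.null(names(paths)) && all(nzchar(names(paths)))) names(paths)
         else tools::file_path_sans_ext(basename(paths))
  tryCatch(
    stackClassifierOutputs(mats, classifierIds = ids,
                           policy = policy, tol = tol),
    error = function(e) {
      # re-raise strict row-sum failures with the offending file named
      msg <- conditionMessage(e)
      if (grepl("^row \\(sample", msg)) {
        k <- as.integer(sub(".*classifier (\\d+)\\).*", "\\1", msg))
        stop(sprintf("%s: %s", paths[k], sub(", classifier \\d+\\)", ")", msg)),
             call. = FALSE)
      }
      stop(e)
    })
}

#' Read a ground-truth labels file
#'
#' @param path CSV with header `sample_id,label`.
#' @param scores optional [ScoreTensor-class]; when given, the sample ids
#'   must match the tensor's exactly and the labels must come from its
#'   class vocabulary.
#' @param classLabels class vocabulary when no tensor is given (default:
#'   the sorted unique labels in the file).
#' @return a [LabelVector-class].
#' @export
readLabelsCsv <- function(path, scores = NULL, classLabels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("sample_id", "label")))
    stop(sprintf("%s: header must be sample_id,label", path))
  if (!is.null(scores)) {
    if (is.null(classLabels)) classLabels <- classLabels(scores)
    if (!identical(as.character(df$sample_id), sampleIds(scores)))
      stop(sprintf("%s: sample ids do not match the score files", path))
  }
  if (is.null(classLabels)) classLabels <- sort(unique(as.character(df$label)))
  labelVector(as.character(df$label), classLabels)
}

#' Write per-classifier score files and a labels file
#'
#' Inverse of [readScoresCsv()]/[readLabelsCsv()]; scores are printed with
#' 6 significant digits, files are deterministic and newline-terminated.
#'
#' @param scores a [ScoreTensor-class].
#' @param dir output directory (created if missing).
#' @param truth optional [LabelVector-class] written to `labels.csv`.
#' @return invisibly, the paths written (named `scores` and `labels`).
#' @export
writeScoresCsv <- function(scores, dir, truth = NULL) {
  stopifnot(is(scores, "ScoreTensor"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (n in seq_len(nClassifiers(scores))) {
    m <- classifierMatrix(scores, n)
    df <- data.frame(sample_id = rownames(m),
                     signif(m, 6), check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, paste0("scores_", classifierIds(scores)[n], ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  names(paths) <- classifierIds(scores)
  out <- list(scores = paths, labels = NULL)
  if (!is.null(truth)) {
    lp <- file.path(dir, "labels.csv")
    df <- data.frame(sample_id = sampleIds(scores),
                     label = classLabels(truth)[classIndices(truth)],
                     stringsAsFactors = FALSE)
    utils::write.csv(df, lp, row.names = FALSE, quote = FALSE)
    out$labels <- lp
  }
  invisible(out)
}

#' Write fused predictions to CSV
#'
#' Columns: `sample_id`, `predicted_label`, then one fused-score column
#' per class (6 significant digits).
#'
#' @param result a [FusionResult-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writePredictionsCsv <- function(result, path) {
  stopifnot(is(result, "FusionResult"))
  fs <- signif(result@fusedScores, 6)
  colnames(fs) <- paste0("fused_", result@classLabels)
  df <- data.frame(sample_id = result@sampleIds,
                   predicted_label = predictedLabels(result),
                   fs, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions file back
#'
#' @param path a file written by [writePredictionsCsv()].
#' @return a data.frame with `sample_id`, `predicted_label` and the fused
#'   score columns.
#' @export
readPredictionsCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("sample_id", "predicted_label")))
    stop(sprintf("%s: header must start sample_id,predicted_label", path))
  df
}

#' Write an evaluation report (or comparison table) to CSV
#'
#' Full precision is kept in the file; use [formatReportTable()] first for
#' a display-rounded variant.
#'
#' @param report an [EvaluationReport-class], a named list of them, or a
#'   data.frame from [reportTable()].
#' @param path output file.
#' @param model model name used when a single report is given.
#' @return invisibly, `path`.
#' @export
writeReportCsv <- function(report, path, model = "model") {
  if (is(report, "EvaluationReport"))
    report <- reportTable(stats::setNames(list(report), model))
  else if (is.list(report) && !is.data.frame(report))
    report <- reportTable(report)
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
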