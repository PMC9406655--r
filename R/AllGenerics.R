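#' @rdname ScoreTensor-class
#' @param object,x an object.
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname ScoreTensor-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ScoreTensor-class
#' @export
setGeneric("classifierIds", function(object) standardGeneric("classifierIds"))

#' @rdname ScoreTensor-class
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname ScoreTensor-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname ScoreTensor-class
#' @export
setGeneric("nClassifiers", function(object) standardGeneric("nClassifiers"))

#' @rdname ScoreTensor-class
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))

#' @rdname FusionResult-class
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname FusionResult-class
#' @export
setGeneric("fusedScores", function(object) standardGeneric("fusedScores"))

#' @rdname FusionResult-class
#' @export
setGeneric("predictedLabels", function(object) standardGeneric("predictedLabels"))

#' Measure of a classifier subset under a lambda-fuzzy measure
#'
#' @param measure a [LambdaFuzzyMeasure-class].
#' @param subset integer indices of the classifiers in the subset (possibly
#'   empty).
#' @return the subset's measure in `[0, 1]`.
#' @export
setGeneric("measureOf", function(measure, subset) standardGeneric("measureOf"))
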