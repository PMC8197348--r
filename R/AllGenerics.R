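#' @rdname EEGRecord
#' @param object,x an object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname EEGRecord
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecord
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname EEGRecord
#' @export
setGeneric("stageAnnotations", function(x) standardGeneric("stageAnnotations"))

#' @rdname CBFTrace
#' @export
setGeneric("baselineValue", function(x) standardGeneric("baselineValue"))

#' @rdname AnimalSession
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname AnimalSession
#' @export
setGeneric("timeline", function(x) standardGeneric("timeline"))

#' @rdname AnimalSession
#' @export
setGeneric("pauses", function(x) standardGeneric("pauses"))

#' @rdname AnimalSession
#' @export
setGeneric("roscStage", function(x) standardGeneric("roscStage"))

#' @rdname AnimalSession
#' @export
setGeneric("eeg", function(x) standardGeneric("eeg"))

#' @rdname AnimalSession
#' @export
setGeneric("cbf", function(x) standardGeneric("cbf"))

#' @rdname QEEGFeatureSet
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Continuous class-1 scores from a trained classifier
#'
#' @param model a [TrainedClassifier-class].
#' @param X numeric feature matrix (columns must match the training
#'   features).
#' @return numeric scores in `[0, 1]`, monotone in class-1 confidence; the
#'   default decision threshold is 0.5.
#' @export
setGeneric("predictScores", function(model, X) standardGeneric("predictScores"))

#' Scalar metrics from a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric: accuracy, sensitivity, specificity, precision,
#'   f1.  Ratios with a zero denominator are returned as `NA` with a
#'   warning, never silently zero.
#' @export
setGeneric("classifierMetrics", function(cm) standardGeneric("classifierMetrics"))
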