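#' @rdname EEGRecord
setMethod("samples", "EEGRecord", function(x) x@samples)

#' @rdname CBFTrace
setMethod("samples", "CBFTrace", function(x) x@samples)

#' @rdname EEGRecord
setMethod("samplingRate", "EEGRecord", function(x) x@fs)

#' @rdname CBFTrace
setMethod("samplingRate", "CBFTrace", function(x) x@fs)

#' @rdname EEGRecord
setMethod("duration", "EEGRecord", function(x) length(x@samples) / x@fs)

#' @rdname CBFTrace
setMethod("duration", "CBFTrace", function(x) length(x@samples) / x@fs)

#' @rdname EEGRecord
setMethod("stageAnnotations", "EEGRecord", function(x) x@annotations)

#' @rdname CBFTrace
setMethod("baselineValue", "CBFTrace", function(x) x@baselineValue)

#' @rdname AnimalSession
setMethod("animalId", "AnimalSession", function(x) x@animalId)

#' @rdname AnimalSession
setMethod("timeline", "AnimalSession", function(x) x@timeline)

#' @rdname AnimalSession
setMethod("pauses", "AnimalSession", function(x) x@pauses)

#' @rdname AnimalSession
setMethod("roscStage", "AnimalSession", function(x) x@roscStage)

#' @rdname AnimalSession
setMethod("eeg", "AnimalSession", function(x) x@eeg)

#' @rdname AnimalSession
setMethod("cbf", "AnimalSession", function(x) x@cbf)

#' @rdname QEEGFeatureSet
#' @param x a QEEGFeatureSet.
setMethod("featureMatrix", "QEEGFeatureSet", function(x)
  SummarizedExperiment::assay(x, "qeeg"))

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf("EEGRecord: %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs, object@t0))
  if (length(object@samples))
    cat(sprintf("  amplitude range: [%.2f, %.2f] uV\n",
                min(object@samples), max(object@samples)))
  if (nrow(object@annotations))
    cat(sprintf("  %d stage annotations (%s)\n", nrow(object@annotations),
                paste(unique(object@annotations$label), collapse = ", ")))
})

setMethod("show", "CBFTrace", function(object) {
  cat(sprintf("CBFTrace: %d samples @ %g Hz (%.2f s), baseline %s mL/min\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              ifelse(is.na(object@baselineValue), "NA",
                     sprintf("%.1f", object@baselineValue))))
})

setMethod("show", "AnimalSession", function(object) {
  outcome <- if (is.na(object@roscStage)) "non-ROSC" else
    sprintf("ROSC (timeline stage %d)", object@roscStage)
  cat(sprintf("AnimalSession '%s': %d stages, %d pre-shock pauses, %s\n",
              object@animalId, nrow(object@timeline),
              nrow(object@pauses), outcome))
  cat(sprintf("  EEG %.1f s @ %g Hz; CBF %.1f s @ %g Hz\n",
              duration(object@eeg), object@eeg@fs,
              duration(object@cbf), object@cbf@fs))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (class 1 = recovered CBF is positive)\n")
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d\n",
              object@tp, object@fn, object@fp, object@tn))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("Leave-one-animal-out evaluation (pooled over folds)\n")
  print(round(object@metrics, 3))
})

setMethod("show", "TrainedClassifier", function(object) {
  cat(sprintf("TrainedClassifier: %s on %d features (seed %d)\n",
              object@kind, length(object@featureNames), object@seed))
})
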