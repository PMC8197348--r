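#' @include utils.R
NULL

.emptyAnnotations <- function() {
  data.frame(label = character(0), start = numeric(0), end = numeric(0),
             stringsAsFactors = FALSE)
}

#' Single-channel EEG recording
#'
#' A uniformly sampled voltage trace in microvolts with its sampling rate,
#' start time and optional stage annotations (protocol stage labels with
#' start/end times in seconds).
#'
#' @slot samples numeric vector of voltages (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot t0 start time of the first sample in seconds.
#' @slot annotations data.frame with columns `label`, `start`, `end`
#'   (seconds), each interval lying inside the record span.
#'
#' @exportClass EEGRecord
setClass("EEGRecord",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 annotations = "data.frame"),
  prototype(samples = numeric(0), fs = 250, t0 = 0,
            annotations = .emptyAnnotations()))

setValidity("EEGRecord", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  ann <- object@annotations
  need <- c("label", "start", "end")
  if (!all(need %in% names(ann))) {
    msg <- c(msg, "'annotations' needs columns label, start, end")
  } else if (nrow(ann)) {
    span0 <- object@t0
    span1 <- object@t0 + length(object@samples) / object@fs
    tol <- 1 / object@fs
    if (any(ann$start < span0 - tol) || any(ann$end > span1 + tol))
      msg <- c(msg, "annotations fall outside the record span")
    if (any(ann$end < ann$start))
      msg <- c(msg, "annotation end precedes start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecord
#'
#' @param samples numeric voltages in microvolts.
#' @param fs sampling rate (Hz).
#' @param t0 start time (s).
#' @param annotations optional stage annotation data.frame
#'   (`label`, `start`, `end`).
#' @return an [EEGRecord-class] object.
#' @examples
#' rec <- EEGRecord(sin(2 * pi * 10 * seq(0, 2, by = 1 / 250)), fs = 250)
#' duration(rec)
#' @export
EEGRecord <- function(samples, fs = 250, t0 = 0,
                      annotations = .emptyAnnotations()) {
  new("EEGRecord", samples = as.numeric(samples), fs = fs, t0 = t0,
      annotations = annotations)
}

#' Carotid blood flow trace
#'
#' @slot samples flow values in mL/min.
#' @slot fs sampling rate in Hz.
#' @slot baselineValue pre-arrest baseline flow (mL/min); must be positive
#'   for sessions that are to be labeled, may be `NA` otherwise.
#'
#' @exportClass CBFTrace
setClass("CBFTrace",
  representation(samples = "numeric", fs = "numeric",
                 baselineValue = "numeric"),
  prototype(samples = numeric(0), fs = 25, baselineValue = NA_real_))

setValidity("CBFTrace", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  bv <- object@baselineValue
  if (length(bv) != 1L || (!is.na(bv) && bv <= 0))
    msg <- c(msg, "'baselineValue' must be a single positive number or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a CBFTrace
#' @param samples flow samples (mL/min).
#' @param fs sampling rate (Hz).
#' @param baselineValue pre-arrest baseline flow (mL/min).
#' @return a [CBFTrace-class] object.
#' @export
CBFTrace <- function(samples, fs = 25, baselineValue = NA_real_) {
  new("CBFTrace", samples = as.numeric(samples), fs = fs,
      baselineValue = as.numeric(baselineValue))
}

#' One animal's VF/CPR session
#'
#' Bundles the protocol timeline, the EEG and CBF signals, the pre-shock
#' pause table and the outcome (index of the stage at which sustained ROSC
#' monitoring began, or `NA` for non-ROSC).
#'
#' @slot animalId character identifier.
#' @slot timeline data.frame with columns `stage`, `start`, `end` (s);
#'   stages are `baseline`, `untreated_vf`, `bls`, `acls`, `pause`,
#'   `monitoring`.
#' @slot eeg an [EEGRecord-class].
#' @slot cbf a [CBFTrace-class] covering the same time span.
#' @slot pauses data.frame with `pause_index`, `start` (s) and
#'   `recovery_rate` (percent, the generator's target rate; observed rates
#'   are recomputed from the CBF trace by [labelPauses()]).
#' @slot roscStage integer timeline row index of the monitoring stage, or
#'   `NA_integer_` for non-ROSC.
#'
#' @exportClass AnimalSession
setClass("AnimalSession",
  representation(animalId = "character", timeline = "data.frame",
                 eeg = "EEGRecord", cbf = "CBFTrace",
                 pauses = "data.frame", roscStage = "integer"))

setValidity("AnimalSession", function(object) {
  msg <- character(0)
  if (length(object@animalId) != 1L || !nzchar(object@animalId))
    msg <- c(msg, "'animalId' must be a single non-empty string")
  need <- c("stage", "start", "end")
  if (!all(need %in% names(object@timeline)))
    msg <- c(msg, "'timeline' needs columns stage, start, end")
  if (!all(c("pause_index", "start", "recovery_rate") %in%
           names(object@pauses)))
    msg <- c(msg, "'pauses' needs columns pause_index, start, recovery_rate")
  eegSpan <- length(object@eeg@samples) / object@eeg@fs
  cbfSpan <- length(object@cbf@samples) / object@cbf@fs
  if (abs(eegSpan - cbfSpan) > 1 / min(object@eeg@fs, object@cbf@fs) + 1e-9)
    msg <- c(msg, sprintf(
      "EEG (%.2f s) and CBF (%.2f s) must cover the same time span",
      eegSpan, cbfSpan))
  if (length(msg)) msg else TRUE
})

#' One-sided power spectrum of a sub-epoch
#'
#' Frequencies in Hz at the periodogram resolution (0.5 Hz for 2-s
#' sub-epochs sampled at 250 Hz) with nonnegative power per bin, scaled so
#' that the total power equals the mean squared amplitude of the
#' (demeaned) signal.  Band powers `P_a-b Hz` are sums over the half-open
#' interval `[a, b)`.
#'
#' @slot freqs frequencies (Hz).
#' @slot power power per bin (microvolt^2).
#'
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "numeric"))

setValidity("PowerSpectrum", function(object) {
  msg <- character(0)
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "'freqs' and 'power' must have equal length")
  if (length(object@power) && any(object@power < -1e-12))
    msg <- c(msg, "'power' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Feature table container
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' single assay `qeeg` holds the quantitative-EEG parameters (rows =
#' features, columns = sub-epochs) and whose column data carries
#' `animal_id`, `pause_index`, `subepoch_index` (0, 1, 2), `recovery_rate`
#' (percent) and `group` (0 = CBF recovery below 30 percent, 1 = at or
#' above it).
#'
#' @exportClass QEEGFeatureSet
setClass("QEEGFeatureSet", contains = "SummarizedExperiment")

setValidity("QEEGFeatureSet", function(object) {
  msg <- character(0)
  if (!"qeeg" %in% SummarizedExperiment::assayNames(object))
    return("assay 'qeeg' is missing")
  m <- SummarizedExperiment::assay(object, "qeeg")
  if (is.null(rownames(m)))
    msg <- c(msg, "feature (row) names are required")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "feature values must be finite (no missing values)")
  cd <- SummarizedExperiment::colData(object)
  need <- c("animal_id", "pause_index", "subepoch_index",
            "recovery_rate", "group")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    msg <- c(msg, paste("colData is missing:", paste(miss, collapse = ", ")))
  if (!length(miss) && ncol(object)) {
    if (!all(cd$group %in% c(0, 1)))
      msg <- c(msg, "'group' must be 0 or 1")
    if (!all(cd$subepoch_index %in% 0:2))
      msg <- c(msg, "'subepoch_index' must be 0, 1 or 2")
    key <- paste(cd$animal_id, cd$pause_index)
    tab <- table(key)
    if (any(tab != 3L))
      msg <- c(msg, "each (animal, pause) must contribute exactly 3 sub-epochs")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QEEGFeatureSet
#'
#' @param features numeric matrix, features x sub-epochs, with row names.
#' @param colData data.frame or DataFrame with the per-sub-epoch metadata
#'   (`animal_id`, `pause_index`, `subepoch_index`, `recovery_rate`,
#'   `group`).
#' @param metadata optional list stored in the object metadata.
#' @return a [QEEGFeatureSet-class].
#' @export
QEEGFeatureSet <- function(features, colData, metadata = list()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(qeeg = features),
    colData = S4Vectors::DataFrame(colData, check.names = FALSE),
    metadata = metadata)
  new("QEEGFeatureSet", se)
}

#' A fitted binary CBF classifier
#'
#' Stores the classifier kind, its pinned hyperparameters, the fitted
#' backend object, the training-set standardization parameters (scoring
#' always reuses the training-set z-scoring) and the seed used to fit.
#'
#' @slot kind one of `"LR"`, `"SVM"`, `"KNN"`, `"RF"`, `"MLP"`.
#' @slot params hyperparameter list.
#' @slot fit backend-specific fitted state.
#' @slot center,scale training-set feature means and standard deviations.
#' @slot featureNames feature names in training order.
#' @slot seed integer seed used when fitting.
#'
#' @exportClass TrainedClassifier
setClass("TrainedClassifier",
  representation(kind = "character", params = "list", fit = "ANY",
                 center = "numeric", scale = "numeric",
                 featureNames = "character", seed = "integer"))

#' Binary confusion matrix
#'
#' Counts with class 1 (recovered CBF) as "positive".
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(counts < 0L)) "counts must be nonnegative" else TRUE
})

#' Leave-one-animal-out evaluation report
#'
#' Per-model pooled confusion matrices, scalar metrics, ROC curves and the
#' pooled per-instance predictions.
#'
#' @slot metrics data.frame, one row per model plus a `mean` row, with
#'   columns accuracy, sensitivity, specificity, precision, f1, auc.
#' @slot confusion named list of [ConfusionMatrix-class] per model.
#' @slot roc named list of data.frames (`fpr`, `tpr`, `threshold`).
#' @slot predictions data.frame with `model`, `animal_id`, `y`, `score`,
#'   `pred` pooled over all folds.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(metrics = "data.frame", confusion = "list",
                 roc = "list", predictions = "data.frame"))
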