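#' Leave-one-animal-out fold plan
#'
#' One fold per animal: that animal's sub-epochs form the test set and
#' the remaining animals' the training set.  Errors if fewer than two
#' animals are present or if any training set would contain a single
#' class (test sets may be single-class; predictions are pooled across
#' folds before metrics are computed).
#'
#' @param animalIds character vector, one entry per instance.
#' @param y binary labels (0/1) per instance.
#' @return list of folds, each with `animal`, `trainIdx`, `testIdx`.
#' @export
makeLoaoFolds <- function(animalIds, y) {
  animalIds <- as.character(animalIds)
  y <- as.integer(y)
  animals <- unique(animalIds)
  if (length(animals) < 2L)
    stop("leave-one-animal-out needs at least 2 animals", call. = FALSE)
  lapply(animals, function(a) {
    testIdx <- which(animalIds == a)
    trainIdx <- which(animalIds != a)
    if (length(unique(y[trainIdx])) < 2L)
      stop(sprintf(
        "training set with animal '%s' held out contains a single class", a),
        call. = FALSE)
    list(animal = a, trainIdx = trainIdx, testIdx = testIdx)
  })
}

#' Binary confusion matrix from labels and predictions
#'
#' Class 1 (recovered CBF) is "positive".
#'
#' @param yTrue,yPred equal-length vectors of 0/1 labels.
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix01 <- function(yTrue, yPred) {
  if (!length(yTrue)) stop("empty input", call. = FALSE)
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' lengths differ", call. = FALSE)
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  new("ConfusionMatrix",
      tp = sum(yTrue == 1 & yPred == 1),
      tn = sum(yTrue == 0 & yPred == 0),
      fp = sum(yTrue == 0 & yPred == 1),
      fn = sum(yTrue == 1 & yPred == 0))
}

.safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); returning NA", what))
    return(NA_real_)
  }
  num / den
}

#' @rdname classifierMetrics
#' @aliases classifierMetrics,ConfusionMatrix-method
setMethod("classifierMetrics", "ConfusionMatrix", function(cm) {
  tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- (tp + tn) / total
  sens <- .safeRatio(tp, tp + fn, "sensitivity")
  spec <- .safeRatio(tn, tn + fp, "specificity")
  prec <- .safeRatio(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens)) NA_real_ else f1Score(prec, sens)
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1)
})

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * p * r / (p + r)`; `NA` when both are zero.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 score (vectorized).
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the sorted unique score values
#' (plus infinite endpoints), records (FPR, TPR) at each, and integrates
#' the curve by the trapezoid rule.  The resulting AUC equals the
#' normalized Mann-Whitney U statistic of the scores.
#'
#' @param yTrue binary labels (0/1); both classes must be present.
#' @param scores numeric class-1 scores.
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
rocAuc <- function(yTrue, scores) {
  yTrue <- as.integer(yTrue)
  if (length(yTrue) != length(scores))
    stop("'yTrue' and 'scores' lengths differ", call. = FALSE)
  n1 <- sum(yTrue == 1)
  n0 <- sum(yTrue == 0)
  if (n1 == 0 || n0 == 0)
    stop("ROC needs both classes present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & yTrue == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & yTrue == 0) / n0,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Leave-one-animal-out evaluation of the classifier panel
#'
#' For each classifier specification: every fold's training data are
#' SMOTE-balanced (held-out data are never touched), the model is
#' trained, and the held-out animal's sub-epochs are scored.  Because
#' most test animals contribute predominantly one class, per-fold
#' sensitivity or specificity would be undefined; predictions are
#' therefore pooled across all folds into one confusion matrix (at the
#' 0.5 threshold) and one ROC curve per model.  The metrics table gains a
#' final `mean` row with the arithmetic cross-model mean of each metric.
#'
#' @param featureSet a [QEEGFeatureSet-class].
#' @param features feature names to use (default: all rows).  Ignored
#'   when `selector` is given.
#' @param specs classifier specifications
#'   ([defaultClassifierSpecs()] by default).
#' @param seed master seed; per-fold SMOTE and training seeds are derived
#'   from it.
#' @param smote apply SMOTE inside training folds (default TRUE).
#' @param smoteK SMOTE neighbor count.
#' @param threshold decision threshold for the pooled confusion matrix.
#' @param selector optional function `(X, y) -> feature names` applied
#'   inside each training fold (in-fold feature selection, avoiding any
#'   use of held-out data in the selection step).
#' @return an [EvaluationReport-class].
#' @export
evaluateAll <- function(featureSet, features = NULL,
                        specs = defaultClassifierSpecs(), seed = 1L,
                        smote = TRUE, smoteK = 5, threshold = 0.5,
                        selector = NULL) {
  stopifnot(is(featureSet, "QEEGFeatureSet"))
  Xall <- t(featureMatrix(featureSet))
  cd <- SummarizedExperiment::colData(featureSet)
  y <- as.integer(cd$group)
  ids <- as.character(cd$animal_id)
  if (is.null(features)) features <- colnames(Xall)
  if (!all(features %in% colnames(Xall)))
    stop("unknown feature names requested", call. = FALSE)
  folds <- makeLoaoFolds(ids, y)

  metricRows <- list()
  confusion <- list()
  rocs <- list()
  predictions <- list()
  for (m in seq_along(specs)) {
    spec <- specs[[m]]
    name <- names(specs)[m] %||% spec$kind
    score <- rep(NA_real_, length(y))
    for (fIdx in seq_along(folds)) {
      fold <- folds[[fIdx]]
      featsUse <- if (is.null(selector)) features else
        selector(Xall[fold$trainIdx, , drop = FALSE], y[fold$trainIdx])
      Xtr <- Xall[fold$trainIdx, featsUse, drop = FALSE]
      ytr <- y[fold$trainIdx]
      foldSeed <- .deriveSeed(seed, 1000 * m + fIdx)
      if (smote) {
        aug <- smoteAugment(Xtr, ytr, k = smoteK, seed = foldSeed)
        Xtr <- aug$X
        ytr <- aug$y
      }
      model <- trainClassifier(spec, Xtr, ytr, seed = foldSeed)
      score[fold$testIdx] <-
        predictScores(model, Xall[fold$testIdx, featsUse, drop = FALSE])
    }
    pred <- as.integer(score >= threshold)
    cm <- confusionMatrix01(y, pred)
    roc <- rocAuc(y, score)
    metricRows[[name]] <- c(classifierMetrics(cm), auc = roc$auc)
    confusion[[name]] <- cm
    rocs[[name]] <- roc$roc
    predictions[[name]] <- data.frame(model = name, animal_id = ids,
                                      y = y, score = score, pred = pred,
                                      stringsAsFactors = FALSE)
  }
  metrics <- as.data.frame(do.call(rbind, metricRows))
  metrics <- rbind(metrics, mean = colMeans(metrics))
  new("EvaluationReport", metrics = metrics, confusion = confusion,
      roc = rocs, predictions = do.call(rbind, predictions))
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a
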