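#' Full-experiment run configuration
#'
#' Bundles every stage's options into one serializable list; a run is
#' reproducible from the configuration alone (all randomness derives from
#' `seed`).
#'
#' @param seed master seed.
#' @param generator a [generatorConfig()]; defaults to one seeded from
#'   `seed`.
#' @param entropyConvention log-energy entropy convention, see
#'   [signalEntropy()].
#' @param bsrThresholdUv,bsrMinRunSec burst-suppression definition.
#' @param threshold CBF group criterion (percent).
#' @param cbfWindow CBF averaging window (s) before each pause.
#' @param K number of features to keep after selection.
#' @param lambda NCA regularization (`NULL` = `1/n`).
#' @param selectionInFold if TRUE, feature selection is recomputed inside
#'   every training fold instead of once on the full table.  The default
#'   (FALSE) matches the modeled experiment's single whole-cohort
#'   selection; the in-fold variant avoids selection leakage.
#' @param smoteK SMOTE neighbor count.
#' @param classifierSpecs see [defaultClassifierSpecs()].
#' @param outDir optional output directory; when set,
#'   [runExperiment()] writes the cohort manifest and signals, the
#'   feature table, a selection report and the evaluation tables there.
#' @return a named list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, generator = NULL,
                      entropyConvention = c("raw_energy", "probability"),
                      bsrThresholdUv = 5, bsrMinRunSec = 0.5,
                      threshold = 30, cbfWindow = 10,
                      K = 10, lambda = NULL, selectionInFold = FALSE,
                      smoteK = 5,
                      classifierSpecs = defaultClassifierSpecs(),
                      outDir = NULL) {
  entropyConvention <- match.arg(entropyConvention)
  if (is.null(generator)) generator <- generatorConfig(seed = seed)
  .assertFlag(selectionInFold, "selectionInFold")
  .assertNumber(K, "K", 1, 20)
  .assertNumber(threshold, "threshold", 0, 100)
  cfg <- list(seed = as.integer(seed), generator = generator,
              entropyConvention = entropyConvention,
              bsrThresholdUv = bsrThresholdUv,
              bsrMinRunSec = bsrMinRunSec, threshold = threshold,
              cbfWindow = cbfWindow, K = K, lambda = lambda,
              selectionInFold = selectionInFold, smoteK = smoteK,
              classifierSpecs = classifierSpecs, outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

.stageMsg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the whole pipeline
#'
#' Executes every stage in order — simulate, filter/segment/extract,
#' label, select, balance + train + evaluate — and (optionally) writes
#' the stage artifacts to `config$outDir`.  Stage timings are logged via
#' `message()`.
#'
#' @param config a [runConfig()].
#' @param quiet suppress stage messages.
#' @return list with `featureSet` (a [QEEGFeatureSet-class]),
#'   `selection` (weights, p-values, ranking, selected set) and `report`
#'   (an [EvaluationReport-class]).
#' @examples
#' \donttest{
#' res <- runExperiment(runConfig(seed = 1), quiet = TRUE)
#' res$report
#' }
#' @export
runExperiment <- function(config = runConfig(), quiet = FALSE) {
  if (!inherits(config, "RunConfig"))
    stop("'config' must come from runConfig()", call. = FALSE)
  t0 <- proc.time()[3]
  tick <- function(stage) {
    t1 <- proc.time()[3]
    .stageMsg(quiet, "[%s] done in %.1f s", stage, t1 - t0)
    t0 <<- t1
  }

  sessions <- simulateCohort(config$generator)
  tick("simulate")

  featureSet <- buildFeatureSet(sessions, threshold = config$threshold,
                                window = config$cbfWindow,
                                entropyConvention = config$entropyConvention,
                                bsrThresholdUv = config$bsrThresholdUv,
                                bsrMinRunSec = config$bsrMinRunSec)
  tick("extract")

  X <- t(featureMatrix(featureSet))
  y <- SummarizedExperiment::colData(featureSet)$group
  pvals <- ttestPvalues(X, y)
  nca <- ncaRank(X, y, lambda = config$lambda)
  selected <- selectFeatures(nca$ranking, pvals, K = config$K)
  selection <- list(weights = nca$weights, ranking = nca$ranking,
                    p_values = pvals, selected = selected)
  tick("select")

  selector <- if (config$selectionInFold) {
    function(Xtr, ytr) {
      p <- ttestPvalues(Xtr, ytr)
      r <- ncaRank(Xtr, ytr, lambda = config$lambda)$ranking
      selectFeatures(r, p, K = config$K)
    }
  } else NULL
  report <- evaluateAll(featureSet, features = selected,
                        specs = config$classifierSpecs,
                        seed = config$seed, smoteK = config$smoteK,
                        selector = selector)
  tick("evaluate")

  if (!is.null(config$outDir)) {
    dir <- config$outDir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeCohort(sessions, file.path(dir, "cohort"))
    writeFeatureTable(featureSet, file.path(dir, "feature_table.csv"))
    yaml::write_yaml(
      list(selected = as.list(selected),
           ranking = as.list(selection$ranking),
           weights = as.list(round(selection$weights, 6)),
           p_values = as.list(signif(selection$p_values, 4))),
      file.path(dir, "selection_report.yaml"))
    utils::write.csv(cbind(model = rownames(report@metrics),
                           round(report@metrics, 4)),
                     file.path(dir, "evaluation_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(report@predictions,
                     file.path(dir, "predictions.csv"), row.names = FALSE)
    .stageMsg(quiet, "[write] artifacts in %s", dir)
  }
  list(featureSet = featureSet, selection = selection, report = report)
}
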