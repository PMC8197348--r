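# bundled reference tables from the swine VF experiment the pipeline
# models; shipped as plain CSV under inst/extdata

#' Reference feature-selection table
#'
#' The published NCA feature ranks, Student's t-test p-values and
#' selection outcomes for the twenty candidate parameters in the swine
#' resuscitation experiment this pipeline models.  Used to pin the
#' behavior of [selectFeatures()]: the ten selected parameters are the
#' top-ranked significant ones, while e.g. BetaR (rank 4 but p = 0.864)
#' and BSR (p < 0.001 but rank 18) are excluded.
#'
#' P-values reported only as "<0.001" are exposed through `p_upper`, a
#' numeric upper bound (0.001) sufficient for the p < 0.05 filter; the
#' printed string is kept in `p_value`.
#'
#' @return data.frame with columns `feature`, `nca_rank`, `p_value`
#'   (character, as printed), `p_upper` (numeric) and `result`.
#' @export
selectionReference <- function() {
  path <- system.file("extdata", "selection_reference.csv",
                      package = "qeegcpr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- suppressWarnings(as.numeric(df$p_value))
  df$p_upper <- ifelse(is.na(num),
                       as.numeric(sub("^<", "", df$p_value)), num)
  df
}

#' Reference classifier performance table
#'
#' The published pooled performance metrics (accuracy, sensitivity,
#' specificity, precision, F1 score, AUC) of the five classifiers in the
#' modeled experiment.  Used for metric-identity checks: each model's F1
#' must equal the harmonic mean of its precision and sensitivity, and the
#' cross-model metric means must match the reported averages.
#'
#' @return data.frame with a `metric` column and one column per model
#'   (LR, SVM, KNN, RF, MLP).
#' @export
performanceReference <- function() {
  path <- system.file("extdata", "performance_reference.csv",
                      package = "qeegcpr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
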