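#' Extract the feature table for a cohort of sessions
#'
#' Band-passes each session's EEG, cuts every pre-shock pause into three
#' overlapping 2-s sub-epochs, extracts the twenty quantitative-EEG
#' parameters per sub-epoch, and attaches the CBF recovery label computed
#' from the session's flow trace.  Each pause contributes exactly three
#' table columns.
#'
#' @param sessions a single [AnimalSession-class] or a list of them.
#' @param threshold CBF group criterion (percent), see [toGroup()].
#' @param window CBF averaging window (s), see [labelPauses()].
#' @param filter band-pass the EEG first (default TRUE; pass FALSE for
#'   signals already filtered on acquisition).
#' @param low,high filter band edges (Hz).
#' @param entropyConvention see [signalEntropy()].
#' @param bsrThresholdUv,bsrMinRunSec see [burstSuppressionRatio()].
#' @return a [QEEGFeatureSet-class] with one column per sub-epoch.
#' @examples
#' sess <- simulateSession(generatorConfig(seed = 1, forceRoscAfterBls = TRUE))
#' fsSet <- buildFeatureSet(sess)
#' dim(featureMatrix(fsSet))
#' @export
buildFeatureSet <- function(sessions, threshold = 30, window = 10,
                            filter = TRUE, low = 0.5, high = 47,
                            entropyConvention = c("raw_energy",
                                                  "probability"),
                            bsrThresholdUv = 5, bsrMinRunSec = 0.5) {
  entropyConvention <- match.arg(entropyConvention)
  if (is(sessions, "AnimalSession")) sessions <- list(sessions)
  mats <- list()
  cds <- list()
  for (session in sessions) {
    rec <- eeg(session)
    if (filter) rec <- bandpassFilter(rec, low, high)
    labels <- labelPauses(session, threshold, window)
    p <- pauses(session)
    for (i in seq_len(nrow(p))) {
      subs <- segmentPause(rec, p$start[i])
      for (k in 1:3) {
        mats[[length(mats) + 1L]] <- extractFeatureVector(
          subs[[k]], entropyConvention = entropyConvention,
          bsrThresholdUv = bsrThresholdUv, bsrMinRunSec = bsrMinRunSec)
        cds[[length(cds) + 1L]] <- data.frame(
          animal_id = animalId(session),
          pause_index = p$pause_index[i],
          subepoch_index = k - 1L,
          recovery_rate = labels$recovery_rate[i],
          group = labels$group[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(mats))
    stop("no pre-shock pauses found in the supplied sessions",
         call. = FALSE)
  features <- do.call(cbind, mats)
  rownames(features) <- qeegFeatureNames()
  cd <- do.call(rbind, cds)
  colnames(features) <- sprintf("%s_p%d_s%d", cd$animal_id,
                                cd$pause_index, cd$subepoch_index)
  QEEGFeatureSet(features, cd,
                 metadata = list(threshold = threshold, window = window,
                                 entropyConvention = entropyConvention))
}
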