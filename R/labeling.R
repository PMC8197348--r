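#' CBF recovery rate relative to the pre-arrest baseline
#'
#' `100 * cbfDuring / cbfBaseline`, the percentage of baseline carotid
#' flow restored during a specific CPR period.
#'
#' @param cbfDuring mean carotid flow during the CPR period (mL/min).
#' @param cbfBaseline pre-arrest baseline flow (mL/min); must be positive.
#' @return recovery rate in percent.
#' @examples
#' recoveryRate(90, 300)   # 30
#' @export
recoveryRate <- function(cbfDuring, cbfBaseline) {
  if (!is.numeric(cbfBaseline) || any(!is.finite(cbfBaseline)) ||
      any(cbfBaseline <= 0))
    stop("'cbfBaseline' must be positive", call. = FALSE)
  if (!is.numeric(cbfDuring) || any(!is.finite(cbfDuring)))
    stop("'cbfDuring' must be finite", call. = FALSE)
  100 * cbfDuring / cbfBaseline
}

#' Binary CBF recovery group
#'
#' Group 1 when the recovery rate is at or above the threshold (default
#' 30 percent, the level at which cerebral blood flow is considered
#' sufficient for the recovery of brain function), group 0 below it.
#'
#' @param rate recovery rate in percent (nonnegative).
#' @param threshold division criterion in percent.
#' @return integer 0 or 1 (vectorized).
#' @examples
#' toGroup(c(29.999, 30, 100))  # 0 1 1
#' @export
toGroup <- function(rate, threshold = 30) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("'rate' must be a nonnegative percentage", call. = FALSE)
  as.integer(rate >= threshold)
}

#' Label a session's pre-shock pauses from its CBF trace
#'
#' For each pause, the "CBF during the specific CPR period" is
#' operationalized as the mean flow over the `window` seconds immediately
#' preceding the pause onset (the tail of the compression cycle that the
#' defibrillation attempt interrupts); the recovery rate is that mean
#' relative to the session baseline, and the group label applies the
#' threshold.
#'
#' @param session an [AnimalSession-class].
#' @param threshold group criterion in percent.
#' @param window averaging window in seconds before each pause.
#' @return data.frame with `pause_index`, `recovery_rate` (observed,
#'   percent) and `group`.
#' @export
labelPauses <- function(session, threshold = 30, window = 10) {
  stopifnot(is(session, "AnimalSession"))
  .assertNumber(window, "window", 0, Inf, strict = TRUE)
  trace <- cbf(session)
  if (is.na(baselineValue(trace)))
    stop("session CBF trace has no baseline value; cannot label",
         call. = FALSE)
  fs <- samplingRate(trace)
  flows <- samples(trace)
  p <- pauses(session)
  rate <- vapply(seq_len(nrow(p)), function(i) {
    i1 <- round(p$start[i] * fs)
    i0 <- max(1L, i1 - round(window * fs) + 1L)
    recoveryRate(mean(flows[i0:i1]), baselineValue(trace))
  }, numeric(1))
  rate <- pmax(rate, 0)
  data.frame(pause_index = p$pause_index, recovery_rate = rate,
             group = toGroup(rate, threshold))
}
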