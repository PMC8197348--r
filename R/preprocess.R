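#' Zero-phase band-pass filter an EEG record
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase, via [signal::filtfilt]).  The default 0.5-47 Hz band is
#' the acquisition band of the modeled recordings; passband gain at 10 Hz
#' is within +/-5 percent and mains-frequency content at 60 Hz is
#' attenuated by more than 20 dB.
#'
#' @param record an [EEGRecord-class].
#' @param low,high band edges (Hz); requires `fs > 2 * high`.
#' @param order Butterworth prototype order (default 4).
#' @return a filtered [EEGRecord-class] of the same length.
#' @examples
#' rec <- EEGRecord(rep(10, 1000), fs = 250)   # DC offset
#' mean(samples(bandpassFilter(rec)))          # ~0: DC is in the stopband
#' @export
bandpassFilter <- function(record, low = 0.5, high = 47, order = 4) {
  stopifnot(is(record, "EEGRecord"))
  .assertNumber(low, "low", 0, Inf, strict = TRUE)
  .assertNumber(high, "high", low, Inf, strict = TRUE)
  fs <- record@fs
  if (fs <= 2 * high)
    stop(sprintf("sampling rate %g Hz is too low for a %g Hz band edge",
                 fs, high), call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, record@samples)
  EEGRecord(filtered, fs = fs, t0 = record@t0,
            annotations = record@annotations)
}

#' Cut a pre-shock pause into three overlapping 2-s sub-epochs
#'
#' Pauses of about 3 s are segmented into three 2-s sub-epochs with 1.5-s
#' overlap, at offsets 0, 0.5 and 1.0 s (sample offsets 0, `fs/2`, `fs`).
#' Adjacent sub-epochs share `1.5 * fs` samples.
#'
#' @param record an [EEGRecord-class] (typically already band-passed).
#' @param pauseStart pause onset in seconds, relative to the record start.
#' @param pauseLen pause length in seconds; must be at least 3 so three
#'   overlapping windows fit.
#' @return list of three [EEGRecord-class] sub-epochs of `2 * fs` samples.
#' @export
segmentPause <- function(record, pauseStart, pauseLen = 3) {
  stopifnot(is(record, "EEGRecord"))
  .assertNumber(pauseStart, "pauseStart", 0, Inf)
  if (pauseLen < 3)
    stop("'pauseLen' must be at least 3 s to form three overlapping 2-s sub-epochs",
         call. = FALSE)
  fs <- record@fs
  i0 <- round((pauseStart - record@t0) * fs) + 1L
  nWin <- round(2 * fs)
  offsets <- round(c(0, 0.5, 1) * fs)
  if (i0 < 1L || i0 + offsets[3] + nWin - 1L > length(record@samples))
    stop("record does not cover the requested pause window", call. = FALSE)
  lapply(seq_along(offsets), function(k) {
    idx <- i0 + offsets[k] + seq_len(nWin) - 1L
    EEGRecord(record@samples[idx], fs = fs,
              t0 = record@t0 + (i0 - 1L + offsets[k]) / fs)
  })
}

#' One-sided periodogram of a sub-epoch
#'
#' Unwindowed periodogram of the demeaned sub-epoch at the natural
#' resolution `fs / n` (0.5 Hz for 2-s epochs at 250 Hz), scaled so the
#' total power equals the mean squared amplitude of the demeaned signal
#' (Parseval).
#'
#' @param x an [EEGRecord-class] or numeric vector.
#' @param fs sampling rate, taken from the record when available.
#' @return a [PowerSpectrum-class].
#' @export
powerSpectrum <- function(x, fs = 250) {
  if (is(x, "EEGRecord")) {
    fs <- x@fs
    x <- x@samples
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- x - mean(x)
  X <- stats::fft(x)
  nHalf <- floor(n / 2)
  p <- Mod(X[seq_len(nHalf + 1L)])^2 / n^2
  # fold negative frequencies onto the positive axis
  if (n %% 2 == 0) {
    if (nHalf > 1L) p[2:nHalf] <- 2 * p[2:nHalf]
  } else {
    p[-1L] <- 2 * p[-1L]
  }
  new("PowerSpectrum", freqs = (0:nHalf) * fs / n, power = p)
}

#' Band power over a half-open frequency interval
#'
#' Sums spectral power over bins with `a <= f < b`.  The half-open
#' convention makes adjacent bands additive:
#' `bandPower(s, a, c) == bandPower(s, a, b) + bandPower(s, b, c)`.
#'
#' @param spectrum a [PowerSpectrum-class].
#' @param a,b band edges in Hz with `a < b`.
#' @return summed power.
#' @export
bandPower <- function(spectrum, a, b) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  .assertNumber(a, "a", 0, Inf)
  .assertNumber(b, "b", 0, Inf)
  if (a >= b) stop("'a' must be strictly less than 'b'", call. = FALSE)
  sel <- spectrum@freqs >= a & spectrum@freqs < b
  sum(spectrum@power[sel])
}
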