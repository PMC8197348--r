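#' Configuration for the synthetic VF/CPR session generator
#'
#' Returns a validated list of generator parameters.  The defaults encode
#' the resuscitation protocol the package models (1 min untreated VF, four
#' 2-min BLS compression cycles, up to ten 2-min ACLS cycles, ~3-s
#' pre-shock pauses, EEG at 250 Hz) and the amplitude regimes of the four
#' characteristic EEG states: irregular baseline activity exceeding +/-20
#' uV, isoelectric VF below +/-5 uV, periodic CPR compression artifact
#' exceeding +/-50 uV, and recovered mixed-frequency activity whose
#' amplitude and fast (8-47 Hz) power share ramp up with the CBF recovery
#' rate.
#'
#' @param seed master seed; a fixed (seed, config) pair yields
#'   byte-identical cohorts.
#' @param nAnimals number of virtual animals (default 8).
#' @param imbalanceTarget marginal fraction of pauses with recovery below
#'   30 percent drawn by [assignRecovery()]; default 119/225, the class
#'   imbalance of the modeled cohort.
#' @param fsEeg,fsCbf sampling rates (Hz) of the EEG and CBF channels.
#' @param baselineCbf pre-arrest carotid flow (mL/min).
#' @param cbfNoiseSd additive flow noise (mL/min).
#' @param compressionRate mechanical compression rate (per minute).  The
#'   default of 102 is the LUCAS2 device convention; it is a configuration
#'   default, not a protocol constant.
#' @param cprPeakUv peak amplitude of the compression artifact (uV).
#' @param pauseDuration pre-shock pause length (s).
#' @param blsCycles,maxAclsCycles compression cycle counts.
#' @param stageDuration BLS/ACLS cycle length (s).
#' @param baselineDuration,vfDuration,monitoringDuration stage lengths (s).
#' @param baselinePeakUv,isoelectricPeakUv peak-amplitude ranges (uV) for
#'   the baseline and isoelectric regimes.
#' @param ampMinUv,ampGainUv,ampMidpoint,ampScale,ampJitterSd logistic ramp
#'   of pause-EEG peak amplitude (uV) in the recovery rate (percent):
#'   `peak = ampMinUv + ampGainUv * plogis((r - ampMidpoint)/ampScale)`,
#'   with multiplicative log-normal jitter.
#' @param fastFracBase,fastFracGain,fastFracMid,fastFracScale,fastFracJitterSd
#'   logistic ramp of the 8-47 Hz power fraction in the recovery rate.
#' @param slowExp,fastDecayHz spectral shape: slow component proportional
#'   to `f^-slowExp` on 0.5-8 Hz, fast component proportional to
#'   `exp(-(f - 8)/fastDecayHz)` on 8-47 Hz.
#' @param bsMid,bsScale,suppressionGain burst-suppression envelope: the
#'   burst (non-suppressed) time fraction ramps logistically in the
#'   recovery rate; suppressed segments are scaled by `suppressionGain`.
#' @param lowShape,lowScale,highShift,highShape,highScale recovery-rate
#'   draws: low (non-perfusing) rates are Gamma(lowShape, lowScale),
#'   high rates are `highShift + Gamma(highShape, highScale)`.
#' @param nonResponderFraction fraction of animals that never achieve
#'   ROSC and contribute predominantly low-recovery pauses.
#' @param pHighFirst,pHighLater probability that a responder animal's
#'   first / subsequent pause shows a high recovery rate.
#' @param pHighNonResponder same for non-responders (rare strays).
#' @param roscProb probability that a defibrillation attempt at a high
#'   recovery rate achieves ROSC.
#' @param forceRoscAfterBls,forceNonRosc degenerate-protocol switches used
#'   in testing: force ROSC at the first attempt, or suppress ROSC
#'   entirely (full 4 BLS + 10 ACLS, 11 pauses).
#' @return a named list of class `GeneratorConfig`.
#' @examples
#' cfg <- generatorConfig(seed = 1, nAnimals = 2)
#' sess <- simulateSession(cfg, "animal1")
#' sess
#' @export
generatorConfig <- function(seed = 1L,
                            nAnimals = 8L,
                            imbalanceTarget = 119 / 225,
                            fsEeg = 250,
                            fsCbf = 25,
                            baselineCbf = 300,
                            cbfNoiseSd = 8,
                            compressionRate = 102,
                            cprPeakUv = 55,
                            pauseDuration = 3,
                            blsCycles = 4L,
                            maxAclsCycles = 10L,
                            stageDuration = 120,
                            baselineDuration = 30,
                            vfDuration = 60,
                            monitoringDuration = 120,
                            baselinePeakUv = c(24, 35),
                            isoelectricPeakUv = c(2, 4.4),
                            ampMinUv = 1.5,
                            ampGainUv = 21,
                            ampMidpoint = 30,
                            ampScale = 10,
                            ampJitterSd = 0.12,
                            fastFracBase = 0.33,
                            fastFracGain = 0.30,
                            fastFracMid = 30,
                            fastFracScale = 15,
                            fastFracJitterSd = 0.03,
                            slowExp = 1,
                            fastDecayHz = 8,
                            bsMid = 22,
                            bsScale = 6,
                            suppressionGain = 0.18,
                            lowShape = 2,
                            lowScale = 6,
                            highShift = 32,
                            highShape = 2,
                            highScale = 12,
                            nonResponderFraction = 3 / 8,
                            pHighFirst = 0.6,
                            pHighLater = 0.85,
                            pHighNonResponder = 0.03,
                            roscProb = 0.25,
                            forceRoscAfterBls = FALSE,
                            forceNonRosc = FALSE) {
  cfg <- as.list(environment())
  .assertNumber(cfg$imbalanceTarget, "imbalanceTarget", 0, 1, strict = TRUE)
  for (nm in c("fsEeg", "fsCbf", "baselineCbf", "compressionRate",
               "cprPeakUv", "pauseDuration", "stageDuration",
               "baselineDuration", "vfDuration", "monitoringDuration",
               "ampMinUv", "ampGainUv", "ampScale", "fastFracScale",
               "bsScale", "lowShape", "lowScale", "highShape", "highScale",
               "suppressionGain"))
    .assertNumber(cfg[[nm]], nm, 0, Inf, strict = TRUE)
  .assertNumber(cfg$nAnimals, "nAnimals", 1, 1e4)
  .assertNumber(cfg$cbfNoiseSd, "cbfNoiseSd", 0, Inf)
  .assertNumber(cfg$blsCycles, "blsCycles", 1, 100)
  .assertNumber(cfg$maxAclsCycles, "maxAclsCycles", 0, 100)
  if (cfg$pauseDuration < 3)
    stop("'pauseDuration' must be at least 3 s (three overlapping 2-s sub-epochs)",
         call. = FALSE)
  if (length(cfg$baselinePeakUv) != 2L || any(cfg$baselinePeakUv <= 20))
    stop("'baselinePeakUv' must be a range above 20 uV", call. = FALSE)
  if (length(cfg$isoelectricPeakUv) != 2L ||
      any(cfg$isoelectricPeakUv >= 5) || any(cfg$isoelectricPeakUv <= 0))
    stop("'isoelectricPeakUv' must be a range inside (0, 5) uV",
         call. = FALSE)
  .assertFlag(cfg$forceRoscAfterBls, "forceRoscAfterBls")
  .assertFlag(cfg$forceNonRosc, "forceNonRosc")
  if (cfg$forceRoscAfterBls && cfg$forceNonRosc)
    stop("cannot force both ROSC and non-ROSC", call. = FALSE)
  cfg$seed <- as.integer(seed)
  cfg$nAnimals <- as.integer(nAnimals)
  cfg$blsCycles <- as.integer(blsCycles)
  cfg$maxAclsCycles <- as.integer(maxAclsCycles)
  class(cfg) <- "GeneratorConfig"
  cfg
}

# band-limited (0.5-47 Hz) noise with a 1/f-shaped slow component and an
# exponentially decaying fast component; `fastFrac` is the expected share
# of 1-47 Hz power lying in 8-47 Hz.  Returns n samples, unit-free scale.
.synthShapedNoise <- function(n, fs, fastFrac, slowExp = 1, fastDecayHz = 8) {
  stopifnot(n >= 2)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f) * fs / n                 # mirrored FFT frequencies
  S <- numeric(n)
  slow <- f >= 0.5 & f < 8
  fast <- f >= 8 & f <= 47
  S[slow] <- f[slow]^(-slowExp)
  shapeFast <- exp(-(f[fast] - 8) / fastDecayHz)
  sumSlow <- sum(S[f >= 1 & f < 8])
  sumFast <- sum(shapeFast)
  fastFrac <- min(max(fastFrac, 0.02), 0.98)
  gain <- if (sumFast > 0) fastFrac / (1 - fastFrac) * sumSlow / sumFast else 0
  S[fast] <- gain * shapeFast
  x <- stats::rnorm(n)
  Re(stats::fft(stats::fft(x) * sqrt(S), inverse = TRUE)) / n
}

# burst-suppression envelope: alternating burst (gain 1) and suppression
# (gain `suppressionGain`) segments with ~40 ms cosine ramps
.burstEnvelope <- function(n, fs, burstFrac, suppressionGain) {
  env <- numeric(0)
  inBurst <- stats::runif(1) < burstFrac
  while (length(env) < n) {
    if (inBurst) {
      dur <- stats::runif(1, 0.3, 0.9)
      gain <- 1
    } else {
      dur <- stats::runif(1, 0.3, 0.9) * (1 - burstFrac) /
        max(burstFrac, 0.05)
      dur <- min(max(dur, 0.5), 4)
      gain <- suppressionGain
    }
    env <- c(env, rep(gain, round(dur * fs)))
    inBurst <- !inBurst
  }
  env <- env[seq_len(n)]
  ramp <- max(3L, round(0.04 * fs))
  kern <- (1 - cos(pi * seq_len(ramp) / ramp)) / 2
  kern <- kern / sum(kern)
  as.numeric(stats::filter(c(rep(env[1], ramp), env, rep(env[n], ramp)),
                           kern, sides = 2))[ramp + seq_len(n)]
}

.scaleToPeak <- function(x, peak) {
  m <- max(abs(x))
  if (m <= 0) return(x)
  x * (peak / m)
}

#' Synthesize pause EEG for one regime
#'
#' Generates band-limited (0.5-47 Hz) colored-noise EEG for one of the
#' three compression-free regimes: `baseline` (irregular activity with
#' peak amplitude above 20 uV), `isoelectric` (peak amplitude strictly
#' below 5 uV) and `recovered` (amplitude and 8-47 Hz power share ramp
#' logistically with `recoveryRate`; below roughly 35 percent recovery the
#' signal alternates suppression and brief bursts).
#'
#' @param regime `"baseline"`, `"isoelectric"` or `"recovered"`.
#' @param recoveryRate CBF recovery rate in percent; required for the
#'   `recovered` regime.
#' @param duration length in seconds (at least 2).
#' @param fs sampling rate (Hz).
#' @param config a [generatorConfig()] supplying the regime parameters.
#' @param seed optional seed; omit to draw from the caller's RNG stream.
#' @return an [EEGRecord-class] annotated with the regime.
#' @examples
#' iso <- synthEegPause("isoelectric", duration = 3, seed = 1)
#' max(abs(samples(iso))) < 5
#' @export
synthEegPause <- function(regime = c("baseline", "isoelectric", "recovered"),
                          recoveryRate = NA_real_, duration = 3, fs = 250,
                          config = generatorConfig(), seed = NULL) {
  regime <- match.arg(regime)
  .assertNumber(duration, "duration", 2, Inf)
  n <- round(duration * fs)
  .withSeed(seed, {
    if (regime == "baseline") {
      frac <- min(max(stats::rnorm(1, 0.45, 0.02), 0.3), 0.6)
      x <- .synthShapedNoise(n, fs, frac, config$slowExp, config$fastDecayHz)
      x <- .scaleToPeak(x, stats::runif(1, config$baselinePeakUv[1],
                                        config$baselinePeakUv[2]))
    } else if (regime == "isoelectric") {
      frac <- min(max(stats::rnorm(1, 0.40, 0.02), 0.3), 0.6)
      x <- .synthShapedNoise(n, fs, frac, config$slowExp, config$fastDecayHz)
      x <- x * .burstEnvelope(n, fs, stats::runif(1, 0.2, 0.45),
                              config$suppressionGain)
      x <- .scaleToPeak(x, stats::runif(1, config$isoelectricPeakUv[1],
                                        config$isoelectricPeakUv[2]))
    } else {
      if (!is.finite(recoveryRate) || recoveryRate < 0)
        stop("'recoveryRate' must be a nonnegative percentage for the recovered regime",
             call. = FALSE)
      r <- recoveryRate
      frac <- config$fastFracBase +
        config$fastFracGain * .logistic(r, config$fastFracMid,
                                        config$fastFracScale) +
        stats::rnorm(1, 0, config$fastFracJitterSd)
      frac <- min(max(frac, 0.1), 0.85)
      x <- .synthShapedNoise(n, fs, frac, config$slowExp, config$fastDecayHz)
      burstFrac <- 0.12 + 0.88 * .logistic(r, config$bsMid, config$bsScale)
      if (burstFrac < 0.93)
        x <- x * .burstEnvelope(n, fs, burstFrac, config$suppressionGain)
      peak <- (config$ampMinUv +
                 config$ampGainUv * .logistic(r, config$ampMidpoint,
                                              config$ampScale)) *
        exp(stats::rnorm(1, 0, config$ampJitterSd))
      x <- .scaleToPeak(x, peak)
    }
    EEGRecord(x, fs = fs,
              annotations = data.frame(label = regime, start = 0,
                                       end = n / fs))
  })
}

#' Synthesize periodic CPR compression artifact
#'
#' A periodic waveform at the compression fundamental (`rate`/60 Hz) with
#' decaying harmonics, random phases and a small broadband noise floor,
#' scaled so the peak amplitude exceeds `amplitude`.
#'
#' @param rate compression rate per minute (> 0).
#' @param amplitude minimum peak amplitude (uV).
#' @param duration length (s).
#' @param fs sampling rate (Hz).
#' @param seed optional seed.
#' @return an [EEGRecord-class].
#' @export
synthCprArtifact <- function(rate = 102, amplitude = 55, duration = 10,
                             fs = 250, seed = NULL) {
  .assertNumber(rate, "rate", 0, Inf, strict = TRUE)
  .assertNumber(amplitude, "amplitude", 0, Inf, strict = TRUE)
  .assertNumber(duration, "duration", 0, Inf, strict = TRUE)
  f0 <- rate / 60
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  .withSeed(seed, {
    amps <- c(1, 0.5, 0.25, 0.12, 0.06)
    phases <- stats::runif(5, 0, 2 * pi)
    x <- rowSums(vapply(1:5, function(h)
      amps[h] * sin(2 * pi * h * f0 * t + phases[h]), numeric(n)))
    x <- x + stats::rnorm(n, 0, 0.04)
    EEGRecord(.scaleToPeak(x, amplitude * 1.04), fs = fs,
              annotations = data.frame(label = "cpr_artifact", start = 0,
                                       end = n / fs))
  })
}

#' Draw a CBF recovery rate for one pre-shock pause
#'
#' With no `flowLevel`, draws from a two-component mixture: with
#' probability `config$imbalanceTarget` a low (non-perfusing) rate from
#' Gamma(`lowShape`, `lowScale`), otherwise a high rate
#' `highShift + Gamma(highShape, highScale)`, so the marginal fraction of
#' rates below 30 percent approximates the configured imbalance.  With a
#' `flowLevel` (mL/min) the rate is computed deterministically against the
#' configured baseline flow.
#'
#' @param config a [generatorConfig()].
#' @param pauseIndex pause number (>= 1); the marginal draw does not
#'   depend on it.
#' @param flowLevel optional carotid flow (mL/min) to convert directly.
#' @param seed optional seed.
#' @return recovery rate in percent (nonnegative).
#' @examples
#' assignRecovery(generatorConfig(), 1, flowLevel = 300)  # 100
#' assignRecovery(generatorConfig(), 1, flowLevel = 0)    # 0
#' @export
assignRecovery <- function(config, pauseIndex = 1L, flowLevel = NULL,
                           seed = NULL) {
  .assertNumber(pauseIndex, "pauseIndex", 1, Inf)
  if (!is.null(flowLevel)) {
    .assertNumber(flowLevel, "flowLevel", 0, Inf)
    return(100 * flowLevel / config$baselineCbf)
  }
  .withSeed(seed, {
    if (stats::runif(1) < config$imbalanceTarget)
      stats::rgamma(1, shape = config$lowShape, scale = config$lowScale)
    else
      config$highShift +
        stats::rgamma(1, shape = config$highShape, scale = config$highScale)
  })
}

# per-animal pause recovery rates and outcome under the protocol state
# machine; returns list(rates, roscAttempt or NA)
.drawTrajectory <- function(config, responder) {
  maxAttempts <- 1L + config$maxAclsCycles
  if (config$forceRoscAfterBls) {
    r <- config$highShift +
      stats::rgamma(1, shape = config$highShape, scale = config$highScale)
    return(list(rates = r, roscAttempt = 1L))
  }
  rates <- numeric(0)
  for (attempt in seq_len(maxAttempts)) {
    pHigh <- if (!responder) config$pHighNonResponder
             else if (attempt == 1L) config$pHighFirst
             else config$pHighLater
    high <- stats::runif(1) < pHigh
    r <- if (high)
      config$highShift +
        stats::rgamma(1, shape = config$highShape, scale = config$highScale)
    else
      stats::rgamma(1, shape = config$lowShape, scale = config$lowScale)
    rates <- c(rates, r)
    if (!config$forceNonRosc && r >= 30 && stats::runif(1) < config$roscProb)
      return(list(rates = rates, roscAttempt = attempt))
  }
  list(rates = rates, roscAttempt = NA_integer_)
}

#' Simulate one animal's VF/CPR session
#'
#' Runs the protocol state machine (baseline, 1 min untreated VF, a block
#' of BLS compression cycles ending in the first defibrillation attempt,
#' then ACLS cycles each ending in an attempt, up to
#' `config$maxAclsCycles`; non-ROSC is declared if the last attempt
#' fails), synthesizing consistent EEG and CBF signals throughout.  Each
#' pre-shock pause's EEG regime and the CBF level of the compression stage
#' preceding it are driven by the same drawn recovery rate.
#'
#' @param config a [generatorConfig()].
#' @param animalId animal identifier; together with `config$seed` it
#'   determines the session deterministically.
#' @param responder force responder (TRUE) / non-responder (FALSE) status
#'   instead of drawing it; used by [simulateCohort()].
#' @param seed optional seed override.
#' @return an [AnimalSession-class].
#' @export
simulateSession <- function(config, animalId = "animal1", responder = NULL,
                            seed = NULL) {
  if (!inherits(config, "GeneratorConfig"))
    stop("'config' must come from generatorConfig()", call. = FALSE)
  if (is.null(seed))
    seed <- .deriveSeed(config$seed, .stringSeed(animalId))
  .withSeed(seed, {
    if (is.null(responder))
      responder <- stats::runif(1) >= config$nonResponderFraction
    traj <- .drawTrajectory(config, responder)
    nAttempts <- length(traj$rates)

    stage <- c("baseline", "untreated_vf", rep("bls", config$blsCycles),
               "pause")
    stageRate <- c(NA, NA, rep(traj$rates[1], config$blsCycles),
                   traj$rates[1])
    if (nAttempts > 1L) for (k in 2:nAttempts) {
      stage <- c(stage, "acls", "pause")
      stageRate <- c(stageRate, traj$rates[k], traj$rates[k])
    }
    rosc <- !is.na(traj$roscAttempt)
    if (rosc) {
      stage <- c(stage, "monitoring")
      stageRate <- c(stageRate, NA)
    }
    dur <- vapply(stage, function(s) switch(s,
      baseline = config$baselineDuration,
      untreated_vf = config$vfDuration,
      bls = , acls = config$stageDuration,
      pause = config$pauseDuration,
      monitoring = config$monitoringDuration), numeric(1))
    tl <- data.frame(stage = stage,
                     start = cumsum(c(0, dur[-length(dur)])),
                     end = cumsum(dur), stringsAsFactors = FALSE)

    fsE <- config$fsEeg
    eegParts <- vector("list", nrow(tl))
    cbfParts <- vector("list", nrow(tl))
    for (i in seq_len(nrow(tl))) {
      s <- tl$stage[i]
      d <- dur[i]
      eegParts[[i]] <- switch(s,
        baseline = samples(synthEegPause("baseline", duration = d, fs = fsE,
                                         config = config)),
        untreated_vf = .vfSegment(config, d),
        bls = , acls = {
          art <- samples(synthCprArtifact(config$compressionRate,
                                          config$cprPeakUv, d, fsE))
          art + samples(synthEegPause("isoelectric", duration = d, fs = fsE,
                                      config = config))
        },
        pause = samples(synthEegPause("recovered",
                                      recoveryRate = stageRate[i],
                                      duration = d, fs = fsE,
                                      config = config)),
        monitoring = samples(synthEegPause("recovered",
                                           recoveryRate = stats::runif(1, 85, 105),
                                           duration = d, fs = fsE,
                                           config = config)))
      nC <- round(d * config$fsCbf)
      level <- switch(s,
        baseline = config$baselineCbf,
        untreated_vf = 3,
        bls = , acls = stageRate[i] / 100 * config$baselineCbf,
        pause = 2,
        monitoring = 0.97 * config$baselineCbf)
      cbfParts[[i]] <- pmax(level + stats::rnorm(nC, 0, config$cbfNoiseSd), 0)
    }
    ann <- data.frame(label = tl$stage, start = tl$start, end = tl$end,
                      stringsAsFactors = FALSE)
    eegRec <- EEGRecord(unlist(eegParts), fs = fsE, annotations = ann)
    cbfRec <- CBFTrace(unlist(cbfParts), fs = config$fsCbf,
                       baselineValue = config$baselineCbf)
    pauseRows <- which(tl$stage == "pause")
    pausesDf <- data.frame(pause_index = seq_along(pauseRows),
                           start = tl$start[pauseRows],
                           recovery_rate = traj$rates)
    new("AnimalSession", animalId = animalId, timeline = tl, eeg = eegRec,
        cbf = cbfRec, pauses = pausesDf,
        roscStage = if (rosc) as.integer(nrow(tl)) else NA_integer_)
  })
}

# untreated-VF EEG: baseline-like activity decaying into the isoelectric
# floor over the first ~15 s
.vfSegment <- function(config, duration) {
  fs <- config$fsEeg
  n <- round(duration * fs)
  iso <- samples(synthEegPause("isoelectric", duration = duration, fs = fs,
                               config = config))
  frac <- 0.45
  act <- .synthShapedNoise(n, fs, frac, config$slowExp, config$fastDecayHz)
  act <- .scaleToPeak(act, stats::runif(1, config$baselinePeakUv[1],
                                        config$baselinePeakUv[2]))
  t <- (seq_len(n) - 1) / fs
  iso + act * exp(-t / 4)
}

#' Simulate a cohort of animals
#'
#' Assigns a fixed number of non-responder animals
#' (`round(nAnimals * nonResponderFraction)`, at least one of each type)
#' to random positions and simulates each session.  Most animals therefore
#' contribute predominantly one class, mirroring the per-animal class
#' purity of the modeled experiment.
#'
#' @param config a [generatorConfig()].
#' @return named list of [AnimalSession-class] objects.
#' @examples
#' sessions <- simulateCohort(generatorConfig(seed = 7, nAnimals = 3))
#' vapply(sessions, function(s) nrow(pauses(s)), integer(1))
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "GeneratorConfig"))
    stop("'config' must come from generatorConfig()", call. = FALSE)
  n <- config$nAnimals
  nNon <- max(1L, min(n - 1L, round(n * config$nonResponderFraction)))
  if (n == 1L) nNon <- ifelse(config$nonResponderFraction >= 0.5, 1L, 0L)
  responder <- .withSeed(config$seed,
    sample(rep(c(FALSE, TRUE), c(nNon, n - nNon))))
  ids <- sprintf("animal%d", seq_len(n))
  sessions <- lapply(seq_len(n), function(i)
    simulateSession(config, ids[i], responder = responder[i]))
  names(sessions) <- ids
  sessions
}
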