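# shared fixtures, all generated in code

# pure sinusoid sub-epoch
toneEpoch <- function(freq, amp = 1, n = 500, fs = 250) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
}

makePowerSpectrum <- function(freqs, power) {
  new("PowerSpectrum", freqs = freqs, power = power)
}

# small 4-animal cohort reused across test files (built once per session)
.fixtureCache <- new.env()

demoFeatureSet <- function() {
  if (is.null(.fixtureCache$fs)) {
    cfg <- generatorConfig(seed = 42, nAnimals = 4,
                           nonResponderFraction = 0.5)
    .fixtureCache$fs <- buildFeatureSet(simulateCohort(cfg))
  }
  .fixtureCache$fs
}

# compact session for I/O tests: short stages, one pause, ROSC
smallSession <- function(seed = 11) {
  cfg <- generatorConfig(seed = seed, nAnimals = 1, baselineDuration = 4,
                         vfDuration = 5, stageDuration = 6,
                         monitoringDuration = 4, forceRoscAfterBls = TRUE)
  simulateSession(cfg, "animalA")
}

# the ten parameters kept by the reference selection, with the expected
# sign of the group-1 minus group-0 median difference
selectedSigns <- function() {
  c(Magnitude = 1, DeltaR = 1, DAR = -1, DeltaPR = -1, DTABR = -1,
    BcSEF = 1, BG_Alpha_plus = 1, SpectralEntropy = 1, RenyiEntropy = 1,
    LogEnergyEntropy = 1)
}
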