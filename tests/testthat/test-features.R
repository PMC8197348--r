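test_that("time-domain amplitude features follow their definitions", {
  expect_identical(magnitude(c(-3, 7, -12, 4)), 12)
  expect_identical(magnitude(rep(0, 10)), 0)
  expect_error(magnitude(numeric(0)), "empty")

  x <- c(rep(1, 250), rep(10, 250)) * rep(c(1, -1), 250)
  expect_equal(ratio05(x), 50)
  expect_equal(ratio05(rep(1, 500)), 100)
  # strict inequality at the 5 uV boundary
  expect_equal(ratio05(c(5, -5, 1, 1)), 50)
})

test_that("burst suppression ratio counts only sustained sub-threshold runs", {
  iso <- samples(synthEegPause("isoelectric", duration = 2, seed = 1))
  expect_equal(burstSuppressionRatio(iso), 100)
  # continuous 20 uV oscillation: sub-5 uV crossings are far shorter than 0.5 s
  expect_equal(burstSuppressionRatio(toneEpoch(10, amp = 20)), 0)
  # 1 s suppressed + 1 s burst
  x <- c(rep(0.1, 250), rep(c(20, -20), 125))
  expect_equal(burstSuppressionRatio(x), 50)
})

test_that("log band ratios follow the log10 convention with leakage-tolerant accuracy", {
  # equal powers in numerator and denominator bands
  sp <- makePowerSpectrum(seq(0, 125, 0.5),
                          as.numeric(seq(0, 125, 0.5) %in% c(2, 10)))
  expect_equal(logBandRatio(sp, c(1, 4), c(8, 13)), 0)
  sp10 <- makePowerSpectrum(seq(0, 125, 0.5),
                            10 * (seq(0, 125, 0.5) == 2) +
                              1 * (seq(0, 125, 0.5) == 10))
  expect_equal(logBandRatio(sp10, c(1, 4), c(8, 13)), 1)
  # two-tone signal: amplitude 2 at 2 Hz vs 1 at 10 Hz -> power ratio 4
  x <- 2 * sin(2 * pi * 2 * (0:499) / 250) + toneEpoch(10)
  dar <- logBandRatio(powerSpectrum(x, 250), c(1, 4), c(8, 13))
  expect_equal(dar, log10(4), tolerance = 0.02)
})

test_that("band fractions partition the 1-47 Hz power and match tone placement", {
  sp <- powerSpectrum(toneEpoch(10), 250)
  expect_gte(powerFraction(sp, c(8, 13)), 0.95)
  x <- withr::with_seed(2, rnorm(500))
  spn <- powerSpectrum(x, 250)
  parts <- powerFraction(spn, c(1, 4)) + powerFraction(spn, c(4, 8)) +
    powerFraction(spn, c(8, 13)) + powerFraction(spn, c(13, 30)) +
    powerFraction(spn, c(30, 47))
  expect_equal(parts, 1, tolerance = 1e-9)
  # BG_Alpha+ on its 0-100 scale equals the alpha+beta+gamma share
  v <- extractFeatureVector(x)
  expect_equal(v[["BG_Alpha_plus"]] / 100,
               v[["AlphaPR"]] + v[["BetaPR"]] + v[["GammaPR"]],
               tolerance = 1e-9)
  z <- powerSpectrum(rep(0, 500), 250)
  expect_warning(f <- powerFraction(z, c(8, 13)), "zero total power")
  expect_identical(f, 0)
})

test_that("BcSEF compensates the spectral edge by the suppression fraction", {
  sp10 <- powerSpectrum(toneEpoch(10), 250)
  expect_identical(bcsef(sp10, 100), 0)
  expect_equal(bcsef(sp10, 0), 10, tolerance = 0.5)
  flat <- makePowerSpectrum(seq(0, 125, 0.5),
                            as.numeric(seq(0, 125, 0.5) >= 1 &
                                         seq(0, 125, 0.5) < 47))
  expect_equal(bcsef(flat, 0), 44.5, tolerance = 0.5)
  # monotone nonincreasing in BSR for a fixed spectrum
  bsrs <- seq(0, 100, by = 10)
  vals <- vapply(bsrs, function(b) bcsef(flat, b), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("entropies match their closed forms at uniform and one-hot energy distributions", {
  n <- 500
  uni <- rep(c(3, -3), n / 2)      # equal |x| -> uniform p
  expect_equal(signalEntropy(uni, "shannon"), log(n), tolerance = 1e-9)
  expect_equal(signalEntropy(uni, "renyi"), log(n), tolerance = 1e-9)
  expect_equal(signalEntropy(uni, "log_energy", "probability"),
               -2 * n * log(n), tolerance = 1e-6)
  expect_equal(signalEntropy(uni, "log_energy", "raw_energy"),
               n * log(9), tolerance = 1e-9)
  onehot <- c(7, rep(0, n - 1))    # all energy in one sample
  expect_equal(signalEntropy(onehot, "shannon"), 0, tolerance = 1e-9)
  expect_equal(signalEntropy(onehot, "renyi"), 0, tolerance = 1e-6)
})

test_that("spectral entropy is normalized to [0, 1] with flat and one-bin extremes", {
  f <- seq(0, 125, 0.5)
  flat <- makePowerSpectrum(f, as.numeric(f >= 1 & f < 47))
  expect_equal(spectralEntropy(flat), 1, tolerance = 1e-9)
  single <- makePowerSpectrum(f, as.numeric(f == 10))
  expect_equal(spectralEntropy(single), 0, tolerance = 1e-9)
  expect_identical(spectralEntropy(makePowerSpectrum(f, rep(0, length(f)))), 0)
})

test_that("SynchFastSlow is positive for a tone, zero for silence, stable for noise", {
  expect_gt(synchFastSlow(toneEpoch(10)), 0)
  expect_identical(synchFastSlow(rep(0, 500)), 0)
  vals <- vapply(1:50, function(s)
    synchFastSlow(withr::with_seed(s, rnorm(500))), numeric(1))
  expect_lt(sd(vals), 0.2 * abs(mean(vals)))
})

test_that("amplitude rescaling leaves scale-free features unchanged and scales Magnitude", {
  x <- samples(synthEegPause("recovered", 60, 2, seed = 9))
  c0 <- 3.7
  v1 <- extractFeatureVector(x)
  v2 <- extractFeatureVector(c0 * x)
  scaleFree <- c("ExtraPR", "AlphaPR", "BetaPR", "DeltaPR", "ThetaPR",
                 "GammaPR", "BG_Alpha_plus", "SpectralEntropy",
                 "ShannonEntropy", "RenyiEntropy", "BetaR", "DeltaR",
                 "DAR", "DTABR", "SynchFastSlow")
  expect_equal(v2[scaleFree], v1[scaleFree], tolerance = 1e-9)
  expect_equal(v2[["Magnitude"]], c0 * v1[["Magnitude"]], tolerance = 1e-9)
})

test_that("the full feature vector is complete, deterministic and regime-consistent", {
  iso <- samples(synthEegPause("isoelectric", duration = 2, seed = 4))
  v <- extractFeatureVector(iso)
  expect_identical(names(v), qeegFeatureNames())
  expect_true(all(is.finite(v)))
  expect_equal(v[["BSR"]], 100)
  expect_equal(v[["Ratio05"]], 100)
  expect_identical(v[["BcSEF"]], 0)
  expect_lt(v[["Magnitude"]], 5)

  bl <- samples(synthEegPause("baseline", duration = 2, seed = 4))
  expect_gt(extractFeatureVector(bl)[["Magnitude"]], 20)

  expect_identical(extractFeatureVector(iso), extractFeatureVector(iso))
})
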