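test_that("config validation rejects impossible settings", {
  expect_error(generatorConfig(imbalanceTarget = 0), "imbalanceTarget")
  expect_error(generatorConfig(imbalanceTarget = 1.2), "imbalanceTarget")
  expect_error(generatorConfig(stageDuration = -1), "stageDuration")
  expect_error(generatorConfig(pauseDuration = 2), "pauseDuration")
  expect_error(generatorConfig(forceRoscAfterBls = TRUE,
                               forceNonRosc = TRUE), "both")
})

test_that("forced ROSC after BLS yields one pause then monitoring", {
  cfg <- generatorConfig(seed = 3, forceRoscAfterBls = TRUE)
  s <- simulateSession(cfg, "a1")
  tl <- timeline(s)
  expect_identical(sum(tl$stage == "pause"), 1L)
  expect_identical(tl$stage[nrow(tl)], "monitoring")
  expect_false(is.na(roscStage(s)))
})

test_that("a never-resuscitated session runs the full protocol: 4 BLS, 10 ACLS, 11 pauses", {
  cfg <- generatorConfig(seed = 3, forceNonRosc = TRUE)
  s <- simulateSession(cfg, "a1")
  tl <- timeline(s)
  expect_identical(sum(tl$stage == "bls"), 4L)
  expect_identical(sum(tl$stage == "acls"), 10L)
  expect_identical(sum(tl$stage == "pause"), 11L)
  expect_identical(nrow(pauses(s)), 11L)
  expect_true(is.na(roscStage(s)))
  # protocol stage durations
  expect_true(all(tl$end[tl$stage == "untreated_vf"] -
                    tl$start[tl$stage == "untreated_vf"] == 60))
  expect_true(all(tl$end[tl$stage %in% c("bls", "acls")] -
                    tl$start[tl$stage %in% c("bls", "acls")] == 120))
  # every defibrillation attempt (pause) directly follows a compression cycle
  pauseRows <- which(tl$stage == "pause")
  expect_true(all(tl$stage[pauseRows - 1] %in% c("bls", "acls")))
})

test_that("sessions are deterministic in (seed, config) and EEG/CBF cover the same span", {
  cfg <- generatorConfig(seed = 17, nAnimals = 2)
  s1 <- simulateSession(cfg, "animal1")
  s2 <- simulateSession(cfg, "animal1")
  expect_identical(samples(eeg(s1)), samples(eeg(s2)))
  expect_identical(samples(cbf(s1)), samples(cbf(s2)))
  expect_identical(pauses(s1), pauses(s2))
  expect_equal(duration(eeg(s1)), duration(cbf(s1)), tolerance = 1e-9)
  expect_identical(samplingRate(eeg(s1)), 250)
  # different animals differ
  s3 <- simulateSession(cfg, "animal2")
  expect_false(identical(samples(eeg(s1)), samples(eeg(s3))))
})

test_that("isoelectric pause EEG stays inside the +/-5 uV limits", {
  for (s in 1:5) {
    rec <- synthEegPause("isoelectric", duration = 3, seed = s)
    expect_lt(max(abs(samples(rec))), 5)
  }
})

test_that("baseline EEG exceeds +/-20 uV and the sample count follows duration", {
  rec <- synthEegPause("baseline", duration = 3, seed = 1)
  expect_gt(max(abs(samples(rec))), 20)
  expect_identical(length(samples(rec)), 750L)
  expect_error(synthEegPause("baseline", duration = 1), "duration")
  expect_error(synthEegPause("flatline"), "arg")
})

test_that("recovered EEG amplitude and fast power grow with the recovery rate", {
  stats <- function(rate) {
    vapply(1:50, function(s) {
      x <- samples(synthEegPause("recovered", rate, 2, seed = s))
      sp <- powerSpectrum(x, 250)
      c(mag = max(abs(x)),
        bg = bandPower(sp, 8, 47) / bandPower(sp, 1, 47))
    }, numeric(2))
  }
  hi <- stats(100)
  lo <- stats(10)
  expect_gt(median(hi["mag", ]), median(lo["mag", ]))
  expect_gt(median(hi["bg", ]), median(lo["bg", ]))
})

test_that("CPR artifact is periodic at the compression fundamental with the requested amplitude", {
  rec <- synthCprArtifact(rate = 102, amplitude = 50, duration = 10,
                          seed = 1)
  sp <- powerSpectrum(samples(rec), 250)
  expect_equal(sp@freqs[which.max(sp@power)], 1.7, tolerance = 1e-9)
  expect_gte(max(abs(samples(rec))), 50)
  # different seeds: same fundamental, different waveform (phases)
  rec2 <- synthCprArtifact(rate = 102, amplitude = 50, duration = 10,
                           seed = 2)
  sp2 <- powerSpectrum(samples(rec2), 250)
  expect_equal(sp2@freqs[which.max(sp2@power)], 1.7, tolerance = 1e-9)
  expect_false(identical(samples(rec), samples(rec2)))
})

test_that("marginal recovery-rate draws reproduce the configured class imbalance", {
  cfg <- generatorConfig(seed = 1, imbalanceTarget = 119 / 225)
  rates <- withr::with_seed(123,
    vapply(1:1000, function(i) assignRecovery(cfg, i), numeric(1)))
  expect_true(all(rates >= 0))
  f0 <- mean(rates < 30)
  expect_gte(f0, 0.48)
  expect_lte(f0, 0.58)
  # deterministic flow conversions
  expect_equal(assignRecovery(cfg, 1, flowLevel = cfg$baselineCbf), 100)
  expect_equal(assignRecovery(cfg, 1, flowLevel = 0), 0)
})

test_that("every pause contributes exactly three sub-epochs downstream", {
  fs <- demoFeatureSet()
  cd <- SummarizedExperiment::colData(fs)
  nPauses <- length(unique(paste(cd$animal_id, cd$pause_index)))
  expect_identical(ncol(fs), 3L * nPauses)
  expect_true(all(table(paste(cd$animal_id, cd$pause_index)) == 3))
})
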