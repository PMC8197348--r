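test_that("a simulated session round-trips through manifest + signal files", {
  s <- smallSession()
  dir <- withr::local_tempdir()
  manifest <- writeCohort(s, dir)
  back <- readSession(manifest, "animalA")
  expect_equal(samples(eeg(back)), samples(eeg(s)), tolerance = 1e-6)
  expect_equal(samples(cbf(back)), samples(cbf(s)), tolerance = 1e-6)
  expect_identical(samplingRate(eeg(back)), samplingRate(eeg(s)))
  expect_equal(pauses(back)$start, pauses(s)$start)
  expect_equal(pauses(back)$recovery_rate, pauses(s)$recovery_rate,
               tolerance = 1e-9)
  expect_identical(timeline(back)$stage, timeline(s)$stage)
  expect_identical(roscStage(back), roscStage(s))
  expect_equal(baselineValue(cbf(back)), baselineValue(cbf(s)))
})

test_that("manifest errors name the offending file or field", {
  s <- smallSession()
  dir <- withr::local_tempdir()
  manifest <- writeCohort(s, dir)
  expect_error(readSession(manifest, "nosuch"), "not present")
  expect_error(readSession(file.path(dir, "absent.yaml"), "animalA"),
               "missing")
  # absent signal file
  file.remove(file.path(dir, "animalA_eeg.csv"))
  expect_error(readSession(manifest, "animalA"), "animalA_eeg.csv")
  # malformed header
  manifest2 <- writeCohort(s, dir)
  eegPath <- file.path(dir, "animalA_eeg.csv")
  lines <- readLines(eegPath)
  lines[1] <- "time,volts"
  writeLines(lines, eegPath)
  expect_error(readSession(manifest2, "animalA"), "header")
})

test_that("a sampling-rate mismatch between manifest and file spacing is caught", {
  s <- smallSession()
  dir <- withr::local_tempdir()
  manifest <- writeCohort(s, dir)
  man <- yaml::read_yaml(manifest)
  man$cohort$animals[[1]]$fs_eeg <- 500
  yaml::write_yaml(man, manifest)
  expect_error(readSession(manifest, "animalA"), "fs_eeg")
})

test_that("feature tables round-trip losslessly with a stable column order", {
  fs <- demoFeatureSet()
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(fs, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header, c("animal_id", "pause_index", "subepoch_index",
                             qeegFeatureNames(), "recovery_rate", "group"))
  back <- readFeatureTable(path)
  expect_identical(featureMatrix(back), featureMatrix(fs))
  cdA <- SummarizedExperiment::colData(fs)
  cdB <- SummarizedExperiment::colData(back)
  for (col in c("animal_id", "pause_index", "subepoch_index", "group"))
    expect_equal(as.vector(cdB[[col]]), as.vector(cdA[[col]]))
  expect_identical(cdB$recovery_rate, cdA$recovery_rate)
})

test_that("empty feature tables and malformed cells are handled", {
  featNames <- qeegFeatureNames()
  empty <- QEEGFeatureSet(
    matrix(numeric(0), nrow = 20, ncol = 0,
           dimnames = list(featNames, NULL)),
    data.frame(animal_id = character(0), pause_index = integer(0),
               subepoch_index = integer(0), recovery_rate = numeric(0),
               group = integer(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(empty, path)
  expect_identical(length(readLines(path)), 1L)   # header only
  back <- readFeatureTable(path)
  expect_identical(ncol(back), 0L)

  # non-numeric feature cell
  fs <- demoFeatureSet()
  writeFeatureTable(fs, path)
  lines <- readLines(path)
  lines[2] <- sub("^([^,]*,[^,]*,[^,]*,)[^,]*", "\\1oops", lines[2])
  writeLines(lines, path)
  expect_error(readFeatureTable(path), "non-numeric")

  # duplicate (animal, pause, subepoch) keys
  writeFeatureTable(fs, path)
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(readFeatureTable(path), "duplicate")
})

test_that("EDF export agrees with the text representation within quantization", {
  rec <- synthEegPause("recovered", 55, 3, seed = 6)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_identical(length(samples(back)), length(samples(rec)))
  expect_identical(samplingRate(back), samplingRate(rec))
  quantStep <- 2 * max(abs(samples(rec))) * 1.001 / 65535
  expect_lt(max(abs(samples(back) - samples(rec))), quantStep)
})
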