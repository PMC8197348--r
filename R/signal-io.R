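#' Write a cohort of sessions to disk
#'
#' Writes one structured-text manifest (`manifest.yaml`) per cohort plus,
#' per animal, two delimited-text signal files with mandatory headers:
#' `<id>_eeg.csv` (`t_s, eeg_uV`) and `<id>_cbf.csv` (`t_s, cbf_ml_min`).
#' Comma-separated, '.' decimal, UTF-8.
#'
#' @param sessions an [AnimalSession-class] or list of them.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(sessions, dir) {
  if (is(sessions, "AnimalSession")) sessions <- list(sessions)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(sessions, function(s) {
    id <- animalId(s)
    eegFile <- paste0(id, "_eeg.csv")
    cbfFile <- paste0(id, "_cbf.csv")
    e <- eeg(s)
    .writeSignalCsv(file.path(dir, eegFile),
                    t = e@t0 + (seq_along(samples(e)) - 1) / samplingRate(e),
                    x = samples(e), header = c("t_s", "eeg_uV"))
    tr <- cbf(s)
    .writeSignalCsv(file.path(dir, cbfFile),
                    t = (seq_along(samples(tr)) - 1) / samplingRate(tr),
                    x = samples(tr), header = c("t_s", "cbf_ml_min"))
    tl <- timeline(s)
    p <- pauses(s)
    list(animal_id = id, eeg_file = eegFile, cbf_file = cbfFile,
         fs_eeg = samplingRate(e), fs_cbf = samplingRate(tr),
         baseline_cbf = baselineValue(tr),
         rosc_stage = if (is.na(roscStage(s))) NULL else roscStage(s),
         timeline = list(stage = tl$stage, start = tl$start, end = tl$end),
         pauses = list(pause_index = p$pause_index, start = p$start,
                       recovery_rate = p$recovery_rate))
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(cohort = list(animals = entries)), manifest,
                   precision = 17)
  invisible(manifest)
}

.writeSignalCsv <- function(path, t, x, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(paste(sprintf("%.10g", t), sprintf("%.10g", x), sep = ","),
             con)
}

.readSignalCsv <- function(path, header, fsExpected, what) {
  if (!file.exists(path))
    stop(sprintf("signal file '%s' is missing", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), header))
    stop(sprintf("malformed header in '%s': expected '%s', found '%s'",
                 path, paste(header, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop(sprintf("non-numeric values in '%s'", path), call. = FALSE)
  if (nrow(df) > 1L) {
    fsObs <- 1 / stats::median(diff(df[[1]]))
    if (abs(fsObs - fsExpected) / fsExpected > 1e-6)
      stop(sprintf(
        "%s mismatch for '%s': manifest says %g Hz, file spacing implies %.6g Hz",
        what, path, fsExpected, fsObs), call. = FALSE)
  }
  df
}

#' Read one animal's session from a cohort manifest
#'
#' @param manifestPath path to a `manifest.yaml` written by
#'   [writeCohort()].
#' @param animalId which animal to read; default: the first listed.
#' @return an [AnimalSession-class].
#' @export
readSession <- function(manifestPath, animalId = NULL) {
  if (!file.exists(manifestPath))
    stop(sprintf("manifest '%s' is missing", manifestPath), call. = FALSE)
  man <- yaml::read_yaml(manifestPath)
  entries <- man$cohort$animals
  if (is.null(entries) || !length(entries))
    stop("manifest lists no animals", call. = FALSE)
  ids <- vapply(entries, `[[`, character(1), "animal_id")
  if (is.null(animalId)) animalId <- ids[1]
  i <- match(animalId, ids)
  if (is.na(i))
    stop(sprintf("animal '%s' not present in manifest", animalId),
         call. = FALSE)
  entry <- entries[[i]]
  dir <- dirname(manifestPath)
  eegDf <- .readSignalCsv(file.path(dir, entry$eeg_file),
                          c("t_s", "eeg_uV"), entry$fs_eeg, "fs_eeg")
  cbfDf <- .readSignalCsv(file.path(dir, entry$cbf_file),
                          c("t_s", "cbf_ml_min"), entry$fs_cbf, "fs_cbf")
  tl <- data.frame(stage = unlist(entry$timeline$stage),
                   start = unlist(entry$timeline$start),
                   end = unlist(entry$timeline$end),
                   stringsAsFactors = FALSE)
  pausesDf <- data.frame(pause_index = unlist(entry$pauses$pause_index),
                         start = unlist(entry$pauses$start),
                         recovery_rate = unlist(entry$pauses$recovery_rate))
  ann <- data.frame(label = tl$stage, start = tl$start, end = tl$end,
                    stringsAsFactors = FALSE)
  new("AnimalSession", animalId = animalId, timeline = tl,
      eeg = EEGRecord(eegDf$eeg_uV, fs = entry$fs_eeg,
                      t0 = eegDf$t_s[1], annotations = ann),
      cbf = CBFTrace(cbfDf$cbf_ml_min, fs = entry$fs_cbf,
                     baselineValue = entry$baseline_cbf %||% NA_real_),
      pauses = pausesDf,
      roscStage = if (is.null(entry$rosc_stage)) NA_integer_
                  else as.integer(entry$rosc_stage))
}

#' Read all sessions from a cohort manifest
#'
#' @inheritParams readSession
#' @return named list of [AnimalSession-class] objects.
#' @export
readCohort <- function(manifestPath) {
  man <- yaml::read_yaml(manifestPath)
  ids <- vapply(man$cohort$animals, `[[`, character(1), "animal_id")
  sessions <- lapply(ids, function(id) readSession(manifestPath, id))
  names(sessions) <- ids
  sessions
}

.featureTableColumns <- function() {
  c("animal_id", "pause_index", "subepoch_index", qeegFeatureNames(),
    "recovery_rate", "group")
}

#' Write / read a feature table as delimited text
#'
#' The on-disk format is a comma-separated file with a mandatory header
#' and a stable column order: `animal_id`, `pause_index`,
#' `subepoch_index`, the twenty feature columns in canonical order,
#' `recovery_rate`, `group`.  Numerics are written with 17 significant
#' digits so the round-trip is lossless.
#'
#' @param featureSet a [QEEGFeatureSet-class].
#' @param path output file.
#' @return `writeFeatureTable` invisibly returns `path`;
#'   `readFeatureTable` returns a [QEEGFeatureSet-class].
#' @export
writeFeatureTable <- function(featureSet, path) {
  stopifnot(is(featureSet, "QEEGFeatureSet"))
  cd <- as.data.frame(SummarizedExperiment::colData(featureSet))
  m <- featureMatrix(featureSet)
  df <- cbind(cd[, c("animal_id", "pause_index", "subepoch_index")],
              as.data.frame(t(m)),
              cd[, c("recovery_rate", "group")])
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  out$pause_index <- as.character(cd$pause_index)
  out$subepoch_index <- as.character(cd$subepoch_index)
  out$group <- as.character(cd$group)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("feature table '%s' is missing", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(animal_id = "character"))
  expected <- .featureTableColumns()
  if (!identical(names(df), expected))
    stop("feature table columns do not match the documented format",
         call. = FALSE)
  featCols <- qeegFeatureNames()
  if (nrow(df) == 0L) {
    m <- matrix(numeric(0), nrow = length(featCols), ncol = 0,
                dimnames = list(featCols, NULL))
    cd <- data.frame(animal_id = character(0), pause_index = integer(0),
                     subepoch_index = integer(0),
                     recovery_rate = numeric(0), group = integer(0))
    return(QEEGFeatureSet(m, cd))
  }
  for (nm in c(featCols, "recovery_rate")) {
    if (!is.numeric(df[[nm]]))
      stop(sprintf("non-numeric values in feature column '%s'", nm),
           call. = FALSE)
  }
  key <- paste(df$animal_id, df$pause_index, df$subepoch_index)
  if (anyDuplicated(key))
    stop("duplicate (animal, pause, subepoch) keys in feature table",
         call. = FALSE)
  m <- t(as.matrix(df[, featCols, drop = FALSE]))
  rownames(m) <- featCols
  cd <- df[, c("animal_id", "pause_index", "subepoch_index",
               "recovery_rate", "group")]
  colnames(m) <- sprintf("%s_p%d_s%d", cd$animal_id, cd$pause_index,
                         cd$subepoch_index)
  QEEGFeatureSet(m, cd)
}
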