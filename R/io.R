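# Plain-text interchange: ROI timeseries as TSV (rows = acquisitions,
# columns = ROIs), schedules as BIDS-style events tables (onset/duration in
# seconds, trial_type), embeddings as TSV with JSON diagnostics sidecars.

#' Write / read ROI timeseries as delimited text
#'
#' @param ts a [RoiTimeseries-class].
#' @param path output file (tab-separated; rows = acquisitions, columns =
#'   ROIs, header row of ROI names).
#' @return `writeRoiTimeseries` returns `path` invisibly;
#'   `readRoiTimeseries` returns a [RoiTimeseries-class].
#' @export
writeRoiTimeseries <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeseries"))
  write.table(t(tsData(ts)), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = roiNames(ts))
  invisible(path)
}

#' @rdname writeRoiTimeseries
#' @param tr,subjectId metadata not stored in the table itself.
#' @export
readRoiTimeseries <- function(path, tr = 1.5, subjectId = "sub01") {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  RoiTimeseries(t(as.matrix(x)), tr = tr, subjectId = subjectId)
}

#' Write / read a task schedule as a BIDS-style events table
#'
#' Columns `onset`, `duration` (seconds) and `trial_type`, tab-separated.
#'
#' @param schedule a [TaskSchedule-class].
#' @param path output file.
#' @param tr repetition time used to convert acquisitions to seconds.
#' @return `writeEvents` returns `path` invisibly; `readEvents` a
#'   [TaskSchedule-class].
#' @export
writeEvents <- function(schedule, path, tr = 1.5) {
  ev <- scheduleEvents(schedule)
  out <- data.frame(onset = ev$onset_acq * tr,
                    duration = ev$duration_acq * tr,
                    trial_type = ev$label)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path, tr = 1.5) {
  x <- read.table(path, header = TRUE, sep = "\t")
  TaskSchedule(data.frame(onset_acq = as.integer(round(x$onset / tr)),
                          duration_acq = as.integer(round(x$duration / tr)),
                          label = x$trial_type))
}

#' Write a tvFC matrix as TSV plus JSON sidecar
#'
#' The values go to `<prefix>.tsv` (connections x windows, tab-separated);
#' the connection index, window starts, labels, window spec and flags go
#' to `<prefix>.json`.
#'
#' @param tvfc a [TvfcMatrix-class].
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
writeTvfc <- function(tvfc, prefix) {
  stopifnot(is(tvfc, "TvfcMatrix"))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  write.table(tvfcValues(tvfc), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  spec <- windowSpec(tvfc)
  jsonlite::write_json(list(
    connection_index = connectionIndex(tvfc)[, c("roi_i", "roi_j")],
    window_starts = windowStarts(tvfc),
    window_labels = windowLabels(tvfc),
    w_duration = wDuration(spec), w_step = wStep(spec),
    normalized = isNormalized(tvfc),
    subject_id = subjectId(tvfc)), json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' @rdname writeTvfc
#' @export
readTvfc <- function(prefix) {
  Z <- as.matrix(read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(Z) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  newTvfc(Z, data.frame(roi_i = meta$connection_index$roi_i,
                        roi_j = meta$connection_index$roi_j),
          meta$window_starts, WindowSpec(meta$w_duration, meta$w_step),
          meta$window_labels, meta$normalized,
          subject = meta$subject_id)
}

#' Write an embedding as TSV plus JSON diagnostics sidecar
#'
#' @param emb an [Embedding-class].
#' @param prefix output path prefix; writes `<prefix>.tsv` (window
#'   metadata plus `dim_*` columns) and `<prefix>.json` (method,
#'   hyper-parameters, diagnostics).
#' @return character vector of the two paths, invisibly.
#' @export
writeEmbedding <- function(emb, prefix) {
  stopifnot(is(emb, "Embedding"))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  write.table(cbind(windowData(emb), embeddingCoords(emb)), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = embeddingMethod(emb),
                            hyperparams = hyperParams(emb),
                            diagnostics = diagnostics(emb)),
                       json, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(tsv, json))
}

# lightweight deterministic fingerprint of a numeric matrix (dims,
# Frobenius norm, mean) for ground-truth sidecars
matrixChecksum <- function(x) {
  sprintf("%dx%d:%.12g:%.12g", nrow(x), ncol(x), sqrt(sum(x^2)), mean(x))
}

#' Write a ground-truth sidecar for a synthetic dataset
#'
#' Stores the seeds and per-task covariance checksums of a generated
#' dataset as JSON, so a regenerated dataset can be verified against it.
#'
#' @param groundTruth the `groundTruth` element of one subject from
#'   [generateDataset()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(list(
    seed = groundTruth$seed,
    fingerprint_seed = groundTruth$fingerprintSeed,
    task_covariance_checksums =
      lapply(groundTruth$taskCovariances, matrixChecksum),
    subject_gain_checksum = matrixChecksum(matrix(groundTruth$subjectGains, 1)),
    subject_offset_checksum =
      matrixChecksum(matrix(groundTruth$subjectOffsets, 1))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
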