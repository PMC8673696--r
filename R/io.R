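#' @include AllClasses.R
NULL

#' Construct an MmgRecording
#'
#' @param data channels-by-samples numeric matrix.
#' @param fs sampling rate in Hz (protocol default 1200).
#' @param channels channel metadata data.frame (see [makeSensorArray()]).
#' @param subjectId subject identifier.
#' @param session one of [sessionLabels()].
#' @return a validated [MmgRecording-class].
#' @export
mmgRecording <- function(data, channels, fs = 1200, subjectId = "S01",
                         session = "third_trimester") {
  new("MmgRecording", data = data, fs = fs, channels = channels,
      subjectId = subjectId, session = session)
}

#' Construct an EventList
#'
#' @param onset_s event onsets in seconds (non-decreasing).
#' @param label exercise labels, see [exerciseLabels()].
#' @param duration_s contraction durations in seconds (default 10).
#' @return a validated [EventList-class].
#' @export
eventList <- function(onset_s = numeric(), label = character(),
                      duration_s = 10) {
  n <- length(onset_s)
  new("EventList", entries = data.frame(
    onset_s = as.numeric(onset_s),
    label = as.character(label),
    duration_s = rep_len(as.numeric(duration_s), n),
    stringsAsFactors = FALSE))
}

#' Construct a PipelineConfig
#'
#' All arguments default to the protocol values; see
#' [PipelineConfig-class] for their meaning and units.
#'
#' @param ... named slots to override, e.g. `icaEnabled = FALSE`.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(...) new("PipelineConfig", ...)

## Recording bundle layout -------------------------------------------------
##
## A bundle is a directory holding:
##   data.bin        raw samples, float64 little-endian, column-major over
##                   the channels x samples matrix (channel index fastest)
##   recording.json  sidecar: fs, subject_id, session, n_channels,
##                   n_samples, channels[] (name/role/x/y/z/units)
##   events.tsv      header + one row per event: onset_s, label, duration_s

#' Write a recording bundle to disk
#'
#' Stores the sample matrix as flat binary float64, channel metadata and
#' sampling rate in a JSON sidecar, and the event annotations as TSV. The
#' layout round-trips losslessly through [readRecording()].
#'
#' @param recording an [MmgRecording-class].
#' @param events an [EventList-class].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, events, path) {
  stopifnot(is(recording, "MmgRecording"), is(events, "EventList"))
  validObject(recording); validObject(events)
  ev <- events@entries
  dur <- ncol(recording@data) / recording@fs
  if (nrow(ev) && any(ev$onset_s + ev$duration_s > dur + 1e-9))
    stop("event extends beyond the end of the recording")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(recording@data), con, size = 8, endian = "little")
  sidecar <- list(
    format = "mmglam-bundle-v1",
    fs = recording@fs,
    subject_id = recording@subjectId,
    session = recording@session,
    n_channels = nrow(recording@data),
    n_samples = ncol(recording@data),
    channels = recording@channels)
  jsonlite::write_json(sidecar, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = I(17), dataframe = "rows")
  utils::write.table(ev, file.path(path, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording bundle
#'
#' Reconstructs the [MmgRecording-class] and [EventList-class] written by
#' [writeRecording()], validating every invariant (channel counts, finite
#' samples, role/label vocabularies, event bounds).
#'
#' @param path bundle directory.
#' @return list with elements `recording` and `events`.
#' @export
readRecording <- function(path) {
  sidecarPath <- file.path(path, "recording.json")
  if (!file.exists(sidecarPath)) stop("missing sidecar: ", sidecarPath)
  sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  ch <- as.data.frame(sc$channels, stringsAsFactors = FALSE)
  nch <- sc$n_channels
  ns <- sc$n_samples
  binPath <- file.path(path, "data.bin")
  if (!file.exists(binPath)) stop("missing data file: ", binPath)
  expectBytes <- 8 * nch * ns
  if (file.info(binPath)$size != expectBytes)
    stop(sprintf("channel-count mismatch: sidecar declares %d x %d samples (%d bytes) but data.bin has %d bytes",
                 nch, ns, expectBytes, file.info(binPath)$size))
  con <- file(binPath, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, what = "double", n = nch * ns, size = 8, endian = "little")
  rec <- mmgRecording(matrix(x, nrow = nch, ncol = ns), channels = ch,
                      fs = as.numeric(sc$fs), subjectId = sc$subject_id,
                      session = sc$session)
  validObject(rec)
  evPath <- file.path(path, "events.tsv")
  ev <- if (file.exists(evPath))
    utils::read.table(evPath, header = TRUE, sep = "\t",
                      colClasses = c("numeric", "character", "numeric"),
                      stringsAsFactors = FALSE)
  else data.frame(onset_s = numeric(), label = character(),
                  duration_s = numeric())
  events <- new("EventList", entries = ev)
  validObject(events)
  if (nrow(ev) && any(ev$onset_s + ev$duration_s > ns / sc$fs + 1e-9))
    stop("event extends beyond the end of the recording")
  list(recording = rec, events = events)
}

#' Write a feature table or stats table as CSV
#'
#' @param x data.frame (feature records or paired-stats rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#' @param path CSV path.
#' @return data.frame.
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
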