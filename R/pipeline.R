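#' @include AllClasses.R preprocess.R subtr.R epochs.R features.R stats.R
NULL

#' Run the full preprocessing chain on one recording
#'
#' Stage order follows the acquisition-side processing: SUBTR interference
#' subtraction using the edge-reference sensors (skipped when none are
#' present), band-pass + notch filtering, ICA denoising of the MMG channels
#' (optional), and ECG-referenced cardiac removal from the EMG channels
#' (skipped when no EMG/ECG channels are present).
#'
#' @param recording an [MmgRecording-class].
#' @param config a [PipelineConfig-class].
#' @return list: `recording` (cleaned), `icaReport` ([IcaReport-class] or
#'   NULL), `stages` (character vector of stages actually run).
#' @export
preprocessRecording <- function(recording, config = pipelineConfig()) {
  stages <- character()
  ch <- recording@channels
  if (length(.roleIdx(ch, "mmg_edge_reference"))) {
    filt <- fitSubtr(recording, windowS = config@welchWindowS)
    recording <- applySubtr(recording, filt)
    stages <- c(stages, "subtr")
  }
  recording <- bandpassNotch(recording, config@lowCut, config@highCut,
                             config@filterOrder, config@notchHz)
  stages <- c(stages, "bandpass_notch")
  icaReport <- NULL
  if (config@icaEnabled && length(.roleIdx(ch, "ecg"))) {
    res <- icaDenoise(recording, corrThreshold = config@icaCorrThreshold,
                      seed = config@seed)
    recording <- res$recording
    icaReport <- res$report
    stages <- c(stages, "ica")
  }
  if (length(.roleIdx(ch, "ecg")) && length(.roleIdx(ch, .emgRoles()))) {
    recording <- removeCardiacEmg(recording, windowS = config@welchWindowS)
    stages <- c(stages, "cardiac_emg")
  }
  list(recording = recording, icaReport = icaReport, stages = stages)
}

.configFromList <- function(cfg) {
  pl <- cfg$pipeline
  if (is.null(pl)) pl <- list()
  do.call(pipelineConfig, pl)
}

#' Run the complete study pipeline
#'
#' Simulates a paired pregnancy/postpartum study (or reads existing
#' recording bundles), preprocesses every session, extracts and
#' baseline-corrects moderate-Kegel epochs, applies the SNR quality gate
#' with subject-level exclusion, computes epoch features and per-subject
#' grand averages, and runs the paired statistical comparison. All outputs
#' (feature CSV, stats CSV/JSON, QC report, run manifest) are materialised
#' under `outDir` so each stage is independently re-runnable; the whole run
#' is deterministic given the seed.
#'
#' @param config either a path to a YAML configuration file or an
#'   equivalent nested list (sections: `seed`, `study`, `array`, `session`,
#'   `effect`, `pipeline`, `bundles`).
#' @param outDir output directory (created if needed).
#' @return the run manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
runAll <- function(config, outDir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(cfg$seed)) cfg$seed else 1
  pconf <- .configFromList(cfg)
  pconf@seed <- seed

  # ---- stage 1: obtain sessions --------------------------------------
  if (!is.null(cfg$bundles)) {
    sessions <- lapply(cfg$bundles, readRecording)
    names(sessions) <- vapply(sessions, function(s)
      paste(s$recording@subjectId, s$recording@session, sep = "_"),
      character(1))
    truth <- NULL
  } else {
    st <- cfg$study; if (is.null(st)) st <- list()
    ar <- cfg$array; if (is.null(ar)) ar <- list()
    se <- cfg$session; if (is.null(se)) se <- list()
    ef <- cfg$effect; if (is.null(ef)) ef <- list()
    channels <- do.call(makeSensorArray, ar)
    study <- simulatePairedStudy(
      nSubjects = if (is.null(st$nSubjects)) 9 else st$nSubjects,
      spec = do.call(sessionSpec, se),
      effect = do.call(effectSpec, ef),
      channels = channels,
      baseAmplitude = if (is.null(st$baseAmplitude)) 80 else st$baseAmplitude,
      baseProfile = if (is.null(st$baseProfile)) c(0.5, 0.3, 0.2)
                    else unlist(st$baseProfile),
      seed = seed)
    sessions <- study$sessions
    truth <- study$truth
    writeFeatureTable(truth, file.path(outDir, "ground_truth.csv"))
  }
  .log("pipeline start: %d sessions, seed %d", length(sessions), seed)

  # ---- stages 2-4: preprocess, epoch, QC, features -------------------
  allFeatures <- list(); qcRows <- list(); excluded <- list()
  stagesRun <- NULL
  nExtracted <- 0L; nKept <- 0L
  for (key in names(sessions)) {
    ses <- sessions[[key]]
    prep <- preprocessRecording(ses$recording, pconf)
    stagesRun <- unique(c(stagesRun, prep$stages))
    eps <- extractEpochs(prep$recording, ses$events, labels = "MK",
                         window = pconf@epochWindow)
    eps@epochs <- lapply(eps@epochs, baselineCorrect)
    qc <- qcFilter(eps, pconf@snrThresholdDb)
    nExtracted <- nExtracted + length(eps@epochs)
    nKept <- nKept + length(qc$kept@epochs)
    qcRows[[key]] <- qc$report
    if (nrow(qc$excludedSubjects)) excluded[[key]] <- qc$excludedSubjects
    feats <- epochSetFeatures(qc$kept, pconf)
    if (nrow(feats)) allFeatures[[key]] <- feats
    .log("%s: %d epochs extracted, %d kept", key, length(eps@epochs),
         length(qc$kept@epochs))
  }
  features <- do.call(rbind, allFeatures)
  rownames(features) <- NULL
  writeFeatureTable(features, file.path(outDir, "features.csv"))
  qcReport <- do.call(rbind, qcRows)
  rownames(qcReport) <- NULL
  excludedSubjects <- unique(unlist(lapply(excluded, function(e) e$subject)))
  if (is.null(excludedSubjects)) excludedSubjects <- character()
  jsonlite::write_json(
    list(epochs = qcReport, excluded_subjects = excludedSubjects),
    file.path(outDir, "qc_report.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)

  # ---- stage 5: grand averages + paired statistics -------------------
  summaries <- grandAverage(features, exclude = excludedSubjects)
  stats <- compareSessions(summaries, alpha = pconf@alpha)
  writeFeatureTable(stats, file.path(outDir, "stats.csv"))
  jsonlite::write_json(stats, file.path(outDir, "stats.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- list(
    version = as.character(utils::packageVersion("mmglam")),
    seed = seed,
    config_hash = .confHash(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
    stages_run = stagesRun,
    ica_skipped = !"ica" %in% stagesRun,
    n_sessions = length(sessions),
    n_epochs_extracted = nExtracted,
    n_epochs_kept = nKept,
    excluded_subjects = excludedSubjects,
    n_pairs = if (nrow(stats)) stats$n_pairs[1] else 0L,
    outputs = list(features = "features.csv", stats = "stats.csv",
                   stats_json = "stats.json", qc = "qc_report.json",
                   truth = if (is.null(truth)) NULL else "ground_truth.csv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log("pipeline done: %d/%d epochs kept, %d subject(s) excluded",
       nKept, nExtracted, length(excludedSubjects))
  invisible(manifest)
}
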