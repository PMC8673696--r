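#' @import methods
NULL

## Controlled vocabularies used across the package.

#' Channel roles recognised by the pipeline
#'
#' MMG sensors are split into the lower rows closest to the pelvic floor
#' (`mmg_lower`, the analysis subset), the outer ring used as interference
#' references (`mmg_edge_reference`), and the remainder (`mmg_other`).
#' Auxiliary channels are bipolar surface EMG on perineum, abdomen and thigh,
#' plus one maternal ECG lead.
#'
#' @return Character vector of valid role strings.
#' @export
channelRoles <- function() {
  c("mmg_lower", "mmg_other", "mmg_edge_reference",
    "emg_perineum", "emg_abdomen", "emg_thigh", "ecg")
}

#' Exercise labels of the recording protocol
#'
#' Small / moderate / strong Kegel contractions plus isolated abdominal and
#' thigh contractions, each 10 s long with 10 s intervening rest.
#'
#' @return Character vector of valid event labels.
#' @export
exerciseLabels <- function() c("SmK", "MK", "StK", "A", "T")

#' Session labels of the paired design
#' @return Character vector: third trimester and postpartum.
#' @export
sessionLabels <- function() c("third_trimester", "postpartum")

.mmgRoles <- function() c("mmg_lower", "mmg_other", "mmg_edge_reference")
.emgRoles <- function() c("emg_perineum", "emg_abdomen", "emg_thigh")

.expectedUnits <- function(role) {
  ifelse(role %in% .mmgRoles(), "fT", "uV")
}

.validChannelTable <- function(ch) {
  need <- c("name", "role", "x", "y", "z", "units")
  if (!is.data.frame(ch)) return("channels must be a data.frame")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$name)) return("channel names must be unique")
  bad <- !ch$role %in% channelRoles()
  if (any(bad))
    return(paste("invalid channel role(s):", paste(unique(ch$role[bad]), collapse = ", ")))
  wrongu <- ch$units != .expectedUnits(ch$role)
  if (any(wrongu))
    return(paste("units inconsistent with role for channel(s):",
                 paste(ch$name[wrongu], collapse = ", ")))
  if (!all(is.finite(ch$x)) || !all(is.finite(ch$y)) || !all(is.finite(ch$z)))
    return("channel positions must be finite")
  TRUE
}

#' MmgRecording: a multichannel magnetomyography recording
#'
#' Channels-by-samples matrix together with per-channel metadata (name, role,
#' 3-D position in metres in the array frame, units), the sampling rate and
#' the subject/session identity. MMG channels are in femtotesla, EMG/ECG in
#' microvolts.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz (protocol default 1200).
#' @slot channels data.frame with columns name, role, x, y, z, units.
#' @slot subjectId subject identifier.
#' @slot session one of [sessionLabels()].
#' @export
setClass("MmgRecording",
  representation(data = "matrix", fs = "numeric", channels = "data.frame",
                 subjectId = "character", session = "character"),
  prototype(fs = 1200, subjectId = "S01", session = "third_trimester"))

setValidity("MmgRecording", function(object) {
  msgs <- character()
  ok <- .validChannelTable(object@channels)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (nrow(object@data) != nrow(object@channels))
    msgs <- c(msgs, sprintf("channel count mismatch: %d data rows vs %d channel entries",
                            nrow(object@data), nrow(object@channels)))
  if (length(object@data) && !all(is.finite(object@data)))
    msgs <- c(msgs, "recording contains non-finite samples")
  if (!object@session %in% sessionLabels())
    msgs <- c(msgs, sprintf("session must be one of: %s",
                            paste(sessionLabels(), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' EventList: exercise-onset annotations
#'
#' One row per exercise onset with the onset time in seconds, the exercise
#' label and the contraction duration (protocol default 10 s).
#'
#' @slot entries data.frame with columns onset_s, label, duration_s.
#' @export
setClass("EventList", representation(entries = "data.frame"))

setValidity("EventList", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("onset_s", "label", "duration_s")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$label %in% exerciseLabels()))
      msgs <- c(msgs, sprintf("invalid event label(s): %s",
                              paste(unique(e$label[!e$label %in% exerciseLabels()]),
                                    collapse = ", ")))
    if (is.unsorted(e$onset_s))
      msgs <- c(msgs, "event onsets must be non-decreasing")
    if (any(!is.finite(e$onset_s)) || any(!is.finite(e$duration_s)) ||
        any(e$duration_s <= 0) || any(e$onset_s < 0))
      msgs <- c(msgs, "onsets must be >= 0 and durations > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Epoch: one trigger-locked data segment
#'
#' Channels-by-samples segment covering a fixed window around an exercise
#' onset (default -3 s to +10 s). The pre-trigger part is the baseline
#' interval, the trigger sample and everything after it the signal interval.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate, Hz.
#' @slot channels channel metadata (as in [MmgRecording-class]).
#' @slot label exercise label.
#' @slot window numeric length-2, window in seconds relative to the trigger.
#' @slot subjectId,session provenance.
#' @export
setClass("Epoch",
  representation(data = "matrix", fs = "numeric", channels = "data.frame",
                 label = "character", window = "numeric",
                 subjectId = "character", session = "character"),
  prototype(window = c(-3, 10)))

setValidity("Epoch", function(object) {
  msgs <- character()
  nexp <- round(diff(object@window) * object@fs)
  if (ncol(object@data) != nexp)
    msgs <- c(msgs, sprintf("epoch has %d samples, window implies %d",
                            ncol(object@data), nexp))
  if (nrow(object@data) != nrow(object@channels))
    msgs <- c(msgs, "channel count mismatch")
  if (!object@label %in% exerciseLabels())
    msgs <- c(msgs, "invalid epoch label")
  if (object@window[1] >= 0 || object@window[2] <= 0)
    msgs <- c(msgs, "window must straddle the trigger (start < 0 < end)")
  if (length(msgs)) msgs else TRUE
})

#' EpochSet: a collection of epochs with QC bookkeeping
#'
#' @slot epochs list of [Epoch-class] objects sharing fs and channel set.
#' @slot qc data.frame with one row per epoch (snr_db, kept, ...), possibly
#'   empty before QC has run.
#' @slot provenance list (source, config echo, ...).
#' @export
setClass("EpochSet",
  representation(epochs = "list", qc = "data.frame", provenance = "list"),
  prototype(qc = data.frame(), provenance = list()))

setValidity("EpochSet", function(object) {
  if (!length(object@epochs)) return(TRUE)
  if (!all(vapply(object@epochs, is, logical(1), "Epoch")))
    return("epochs must all be Epoch objects")
  fss <- vapply(object@epochs, function(e) e@fs, numeric(1))
  if (length(unique(fss)) != 1) return("epochs must share a sampling rate")
  nch <- vapply(object@epochs, function(e) nrow(e@data), integer(1))
  if (length(unique(nch)) != 1) return("epochs must share a channel set")
  if (nrow(object@qc) && nrow(object@qc) != length(object@epochs))
    return("qc table must have one row per epoch")
  TRUE
})

#' PipelineConfig: all fixed scalars of the analysis chain
#'
#' Defaults are the protocol values: 20--200 Hz 4th-order Butterworth
#' band-pass, 60 Hz notch, epochs from -3 s to +10 s around the trigger,
#' sliding RMS with 200 ms window and 199 ms overlap smoothed by a 100-point
#' moving average, Welch PSD with 1 s windows at 50% overlap, relative PSD
#' bands 20-80 / 80-140 / 140-200 Hz, SNR gate at 1 dB, alpha 0.05.
#'
#' @export
setClass("PipelineConfig",
  representation(lowCut = "numeric", highCut = "numeric", filterOrder = "numeric",
                 notchHz = "numeric", epochWindow = "numeric",
                 rmsWindowS = "numeric", rmsOverlapS = "numeric",
                 smoothPoints = "numeric", welchWindowS = "numeric",
                 welchOverlap = "numeric", bandEdges = "numeric",
                 snrThresholdDb = "numeric", alpha = "numeric",
                 icaEnabled = "logical", icaCorrThreshold = "numeric",
                 seed = "numeric"),
  prototype(lowCut = 20, highCut = 200, filterOrder = 4, notchHz = 60,
            epochWindow = c(-3, 10), rmsWindowS = 0.2, rmsOverlapS = 0.199,
            smoothPoints = 100, welchWindowS = 1, welchOverlap = 0.5,
            bandEdges = c(20, 80, 140, 200), snrThresholdDb = 1, alpha = 0.05,
            icaEnabled = TRUE, icaCorrThreshold = 0.8, seed = 1))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (object@lowCut <= 0 || object@highCut <= object@lowCut)
    msgs <- c(msgs, "band edges must satisfy 0 < lowCut < highCut")
  if (is.unsorted(object@bandEdges, strictly = TRUE))
    msgs <- c(msgs, "rPSD band edges must be strictly increasing")
  if (any(c(object@rmsWindowS, object@welchWindowS, object@smoothPoints) <= 0))
    msgs <- c(msgs, "window lengths must be positive")
  if (object@rmsOverlapS >= object@rmsWindowS)
    msgs <- c(msgs, "RMS overlap must be shorter than the RMS window")
  if (object@welchOverlap < 0 || object@welchOverlap >= 1)
    msgs <- c(msgs, "welchOverlap must be in [0, 1)")
  if (object@epochWindow[1] >= 0 || object@epochWindow[2] <= 0)
    msgs <- c(msgs, "epoch window must straddle the trigger")
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' SubtrFilter: frequency-dependent subtraction filter
#'
#' Per-frequency complex regression coefficients mapping reference channels
#' to each target channel, estimated in the STFT domain.
#'
#' @slot W complex array, targets x references x frequency bins.
#' @slot freqs frequency grid (Hz) of the STFT bins.
#' @slot windowLength,hop STFT parameters in samples (Hann taper).
#' @slot targetNames,refNames channel names the filter was fitted on.
#' @slot fs sampling rate the filter was fitted at.
#' @export
setClass("SubtrFilter",
  representation(W = "array", freqs = "numeric", windowLength = "numeric",
                 hop = "numeric", targetNames = "character",
                 refNames = "character", fs = "numeric"))

setValidity("SubtrFilter", function(object) {
  if (length(dim(object@W)) != 3) return("W must be a 3-d array")
  if (dim(object@W)[3] != length(object@freqs))
    return("third dimension of W must match the frequency grid")
  if (!all(is.finite(Re(object@W))) || !all(is.finite(Im(object@W))))
    return("W must be finite")
  TRUE
})

#' IcaReport: what the ICA denoising stage decided
#'
#' @slot nComponents number of estimated components.
#' @slot rejected integer indices of rejected components.
#' @slot reasons character, one reason per rejected component
#'   ("ecg_correlated" or "reference_concentrated").
#' @slot varianceRemoved fraction of (centred) data variance removed.
#' @export
setClass("IcaReport",
  representation(nComponents = "numeric", rejected = "integer",
                 reasons = "character", varianceRemoved = "numeric"),
  prototype(rejected = integer(), reasons = character(), varianceRemoved = 0))

setValidity("IcaReport", function(object) {
  if (length(object@rejected) != length(object@reasons))
    return("one reason per rejected component required")
  if (length(object@rejected) &&
      (any(object@rejected < 1) || any(object@rejected > object@nComponents)))
    return("rejected indices out of range")
  TRUE
})

#' PsdResult: a Welch power spectral density estimate
#'
#' @slot freqs one-sided frequency grid in Hz.
#' @slot density power density matrix, channels x frequency (fT^2/Hz for MMG).
#' @slot params list of estimation parameters (window, overlap, taper).
#' @export
setClass("PsdResult",
  representation(freqs = "numeric", density = "matrix", params = "list"))

setValidity("PsdResult", function(object) {
  if (ncol(object@density) != length(object@freqs))
    return("density columns must match the frequency grid")
  if (is.unsorted(object@freqs) || any(object@freqs < 0))
    return("freqs must be non-negative ascending")
  if (any(object@density < -1e-12))
    return("density must be non-negative")
  TRUE
})

## Synthetic-data specification classes -------------------------------------

#' BurstSpec: ground truth for one exercise's contraction bursts
#'
#' A burst is band-limited Gaussian noise mixed from the three analysis bands
#' (20-80 / 80-140 / 140-200 Hz) according to `bandProfile` (power weights
#' summing to 1), scaled so the plateau RMS on the target channel equals
#' `amplitude` (fT), and projected spatially onto channels near the role
#' named by `spatialTarget`.
#'
#' @export
setClass("BurstSpec",
  representation(label = "character", amplitude = "numeric",
                 bandProfile = "numeric", spatialTarget = "character"),
  prototype(label = "MK", amplitude = 80, bandProfile = c(0.5, 0.3, 0.2),
            spatialTarget = "mmg_lower"))

setValidity("BurstSpec", function(object) {
  msgs <- character()
  if (!object@label %in% exerciseLabels()) msgs <- c(msgs, "invalid label")
  if (!is.finite(object@amplitude) || object@amplitude <= 0)
    msgs <- c(msgs, "amplitude must be finite and > 0")
  if (length(object@bandProfile) != 3 || any(object@bandProfile < 0) ||
      abs(sum(object@bandProfile) - 1) > 1e-9)
    msgs <- c(msgs, "bandProfile must be 3 non-negative weights summing to 1")
  if (!object@spatialTarget %in% channelRoles())
    msgs <- c(msgs, "invalid spatialTarget role")
  if (length(msgs)) msgs else TRUE
})

#' SessionSpec: layout and noise levels of one simulated recording
#'
#' Defaults emulate the study protocol: 1200 Hz sampling, 10 s contractions
#' with 10 s intervening rest, 3 cycles per Kegel intensity plus one
#' abdominal and one thigh contraction, thigh/abdominal interference
#' concentrated on the array edge, cardiac artifact, 60 Hz line noise and a
#' broadband sensor noise floor. Levels are RMS amplitudes in fT on the most
#' affected channel.
#'
#' @export
setClass("SessionSpec",
  representation(nCycles = "numeric", restS = "numeric", contractionS = "numeric",
                 fs = "numeric", thighLevel = "numeric", abdomenLevel = "numeric",
                 cardiacLevel = "numeric", lineLevel = "numeric",
                 whiteLevel = "numeric", seed = "numeric"),
  prototype(nCycles = 3, restS = 10, contractionS = 10, fs = 1200,
            thighLevel = 100, abdomenLevel = 60, cardiacLevel = 30,
            lineLevel = 20, whiteLevel = 15, seed = 1))

setValidity("SessionSpec", function(object) {
  msgs <- character()
  if (object@restS <= 0 || object@contractionS <= 0 || object@fs <= 0)
    msgs <- c(msgs, "durations and fs must be > 0")
  if (object@fs <= 400)
    msgs <- c(msgs, "fs must exceed 400 Hz (Nyquist for the 200 Hz band top)")
  if (object@nCycles < 1) msgs <- c(msgs, "nCycles must be >= 1")
  lv <- c(object@thighLevel, object@abdomenLevel, object@cardiacLevel,
          object@lineLevel, object@whiteLevel)
  if (any(lv < 0)) msgs <- c(msgs, "interference levels must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' EffectSpec: the pregnancy-to-postpartum shift injected into a study
#'
#' `rmsRatio` multiplies contraction amplitudes postpartum (< 1 means the
#' postpartum decrease the study observed); `dRpsdL`/`dRpsdM` shift the low
#' and middle band weights additively (the high band absorbs the remainder);
#' `sdBetweenRms` (log-scale SD) and `sdBetweenBand` set between-subject
#' variability of amplitude and band weights.
#'
#' @export
setClass("EffectSpec",
  representation(rmsRatio = "numeric", dRpsdL = "numeric", dRpsdM = "numeric",
                 sdBetweenRms = "numeric", sdBetweenBand = "numeric"),
  prototype(rmsRatio = 0.75, dRpsdL = -0.10, dRpsdM = 0.10,
            sdBetweenRms = 0.2, sdBetweenBand = 0.05))

setValidity("EffectSpec", function(object) {
  msgs <- character()
  if (object@rmsRatio <= 0) msgs <- c(msgs, "rmsRatio must be > 0")
  if (object@sdBetweenRms < 0 || object@sdBetweenBand < 0)
    msgs <- c(msgs, "between-subject SDs must be >= 0")
  if (length(msgs)) msgs else TRUE
})
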