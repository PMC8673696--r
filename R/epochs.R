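#' @include AllClasses.R utils.R
NULL

# Column indices of the baseline / signal intervals of an epoch. The trigger
# sample is the first sample of the signal interval.
.baselineCols <- function(epoch) seq_len(round(-epoch@window[1] * epoch@fs))
.signalCols <- function(epoch) {
  nb <- round(-epoch@window[1] * epoch@fs)
  (nb + 1):ncol(epoch@data)
}

#' Extract trigger-locked epochs from a recording
#'
#' Cuts one fixed window (default -3 s to +10 s) around every selected
#' exercise onset. The trigger sample index is `round(onset_s x fs)`; the
#' window spans `round(13 x fs)` samples of which the first 3 s are the
#' baseline interval. Events whose window exceeds the recording bounds are
#' dropped with a warning; an empty selection yields an empty
#' [EpochSet-class], not an error.
#'
#' @param recording an [MmgRecording-class].
#' @param events an [EventList-class].
#' @param labels exercise labels to keep (default "MK", the analysis set).
#' @param window epoch window in seconds relative to the trigger.
#' @return an [EpochSet-class].
#' @export
extractEpochs <- function(recording, events, labels = "MK",
                          window = c(-3, 10)) {
  fs <- recording@fs
  ev <- events@entries[events@entries$label %in% labels, , drop = FALSE]
  nWin <- round(diff(window) * fs)
  nPre <- round(-window[1] * fs)
  ns <- ncol(recording@data)
  eps <- list()
  dropped <- 0L
  for (r in seq_len(nrow(ev))) {
    trig <- round(ev$onset_s[r] * fs)
    from <- trig - nPre + 1
    to <- from + nWin - 1
    if (from < 1 || to > ns) {
      dropped <- dropped + 1L
      warning(sprintf("event at %.2f s: window [%g, %g] s outside recording, dropped",
                      ev$onset_s[r], window[1], window[2]))
      next
    }
    eps[[length(eps) + 1]] <- new("Epoch",
      data = recording@data[, from:to, drop = FALSE], fs = fs,
      channels = recording@channels, label = ev$label[r], window = window,
      subjectId = recording@subjectId, session = recording@session)
  }
  new("EpochSet", epochs = eps,
      provenance = list(subject = recording@subjectId,
                        session = recording@session,
                        labels = labels, window = window,
                        nEventsSelected = nrow(ev), nDropped = dropped))
}

#' Baseline-correct an epoch
#'
#' Per channel, subtracts the mean of the baseline interval (the pre-trigger
#' 3 s) from the entire epoch, the standard EMG-study baseline correction.
#' After correction the baseline-interval mean is zero per channel.
#'
#' @param epoch an [Epoch-class].
#' @return the corrected [Epoch-class].
#' @export
baselineCorrect <- function(epoch) {
  bl <- rowMeans(epoch@data[, .baselineCols(epoch), drop = FALSE])
  initialize(epoch, data = epoch@data - bl)
}

#' Epoch signal-to-noise ratio in dB
#'
#' SNR is the square of the ratio of signal-interval RMS to
#' baseline-interval RMS, in dB:
#' `10 log10((RMS_sig / RMS_base)^2) = 20 log10(RMS_sig / RMS_base)`.
#' By default RMS pools samples over the `mmg_lower` channel subset (the
#' sensors closest to the pelvic floor); `perChannel = TRUE` instead
#' returns the best single channel's SNR.
#'
#' @param epoch a baseline-corrected [Epoch-class].
#' @param channelRoles channel subset to pool (default `mmg_lower`).
#' @param perChannel if TRUE, return the maximum per-channel SNR instead of
#'   the pooled value.
#' @param capDb value reported when the baseline RMS is zero.
#' @return SNR in dB (scalar).
#' @export
epochSnrDb <- function(epoch, channelRoles = "mmg_lower",
                       perChannel = FALSE, capDb = 300) {
  idx <- .roleIdx(epoch@channels, channelRoles)
  if (!length(idx)) stop("no channels with role(s): ",
                         paste(channelRoles, collapse = ", "))
  sig <- epoch@data[idx, .signalCols(epoch), drop = FALSE]
  base <- epoch@data[idx, .baselineCols(epoch), drop = FALSE]
  snrOne <- function(s, b) {
    rb <- .rmsOf(b)
    if (rb == 0) {
      warning("zero baseline RMS; SNR capped at ", capDb, " dB")
      return(capDb)
    }
    20 * log10(.rmsOf(s) / rb)
  }
  if (perChannel) {
    max(vapply(seq_along(idx),
               function(i) snrOne(sig[i, ], base[i, ]), numeric(1)))
  } else {
    snrOne(sig, base)
  }
}

#' SNR-threshold quality control with subject-level exclusion
#'
#' Discards epochs whose SNR is strictly below `thresholdDb` (epochs at
#' exactly the threshold are kept: only epochs *below* threshold are
#' excluded). Any (subject, session) cell left with zero kept epochs is
#' flagged for subject-level exclusion -- the paired analysis must then
#' drop that subject entirely, since no parameter pair can be formed.
#'
#' @param epochSet an [EpochSet-class] (epochs should be baseline-corrected).
#' @param thresholdDb SNR threshold in dB (study value 1).
#' @param channelRoles passed to [epochSnrDb()].
#' @return list with `kept` (an [EpochSet-class] of surviving epochs, QC
#'   table attached), `report` (per-epoch data.frame: subject, session,
#'   label, snr_db, kept) and `excludedSubjects` (data.frame of
#'   subject/session cells with zero kept epochs).
#' @export
qcFilter <- function(epochSet, thresholdDb = 1, channelRoles = "mmg_lower") {
  n <- length(epochSet@epochs)
  if (!n) {
    return(list(kept = epochSet,
                report = data.frame(subject = character(), session = character(),
                                    label = character(), snr_db = numeric(),
                                    kept = logical()),
                excludedSubjects = data.frame(subject = character(),
                                              session = character())))
  }
  snr <- vapply(epochSet@epochs,
                function(e) epochSnrDb(e, channelRoles), numeric(1))
  # strict "below threshold" exclusion; the tiny tolerance keeps epochs at
  # exactly the threshold from being lost to floating-point rounding
  kept <- snr >= thresholdDb - 1e-9
  report <- data.frame(
    subject = vapply(epochSet@epochs, function(e) e@subjectId, character(1)),
    session = vapply(epochSet@epochs, function(e) e@session, character(1)),
    label = vapply(epochSet@epochs, function(e) e@label, character(1)),
    snr_db = snr, kept = kept, stringsAsFactors = FALSE)
  cells <- unique(report[, c("subject", "session")])
  keptCount <- mapply(function(su, se)
    sum(report$kept[report$subject == su & report$session == se]),
    cells$subject, cells$session)
  excluded <- cells[keptCount == 0, , drop = FALSE]
  rownames(excluded) <- NULL
  if (nrow(excluded))
    .log("subject(s) with no surviving epochs in a session: %s",
         paste(excluded$subject, excluded$session, sep = "/", collapse = ", "))
  keptSet <- epochSet[which(kept)]
  keptSet@qc <- report[kept, , drop = FALSE]
  list(kept = keptSet, report = report, excludedSubjects = excluded)
}
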