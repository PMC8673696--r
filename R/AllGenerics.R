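#' @include AllClasses.R
NULL

#' Sampling rate accessor
#' @param x an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel metadata accessor
#' @param x an object carrying channel metadata.
#' @return data.frame with columns name, role, x, y, z, units.
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' Signal matrix accessor
#' @param x an object carrying a channels-by-samples matrix.
#' @return numeric matrix, channels x samples.
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' Subject identifier accessor
#' @param x an object with subject provenance.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Session accessor (third_trimester / postpartum)
#' @param x an object with session provenance.
#' @export
setGeneric("sessionOf", function(x) standardGeneric("sessionOf"))

#' Event table accessor
#' @param x an [EventList-class].
#' @return data.frame with columns onset_s, label, duration_s.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' QC table accessor
#' @param x an [EpochSet-class].
#' @return data.frame of per-epoch QC results (may be empty before QC).
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))

#' @describeIn MmgRecording-class sampling rate in Hz.
#' @param x an MmgRecording.
#' @export
setMethod("samplingRate", "MmgRecording", function(x) x@fs)
#' @describeIn MmgRecording-class channel metadata table.
#' @export
setMethod("channelInfo", "MmgRecording", function(x) x@channels)
#' @describeIn MmgRecording-class channels-by-samples signal matrix.
#' @export
setMethod("signalData", "MmgRecording", function(x) x@data)
#' @describeIn MmgRecording-class subject identifier.
#' @export
setMethod("subjectId", "MmgRecording", function(x) x@subjectId)
#' @describeIn MmgRecording-class session label.
#' @export
setMethod("sessionOf", "MmgRecording", function(x) x@session)

#' @describeIn Epoch-class sampling rate in Hz.
#' @param x an Epoch.
#' @export
setMethod("samplingRate", "Epoch", function(x) x@fs)
#' @describeIn Epoch-class channel metadata table.
#' @export
setMethod("channelInfo", "Epoch", function(x) x@channels)
#' @describeIn Epoch-class channels-by-samples segment matrix.
#' @export
setMethod("signalData", "Epoch", function(x) x@data)
#' @describeIn Epoch-class subject identifier.
#' @export
setMethod("subjectId", "Epoch", function(x) x@subjectId)
#' @describeIn Epoch-class session label.
#' @export
setMethod("sessionOf", "Epoch", function(x) x@session)

#' @describeIn EventList-class the annotation table.
#' @param x an EventList.
#' @export
setMethod("eventTable", "EventList", function(x) x@entries)

#' @describeIn EpochSet-class per-epoch QC table.
#' @param x an EpochSet.
#' @export
setMethod("qcTable", "EpochSet", function(x) x@qc)

#' Number of epochs in an EpochSet
#' @param x an [EpochSet-class].
#' @export
setMethod("length", "EpochSet", function(x) length(x@epochs))

#' Extract one epoch
#' @param x an [EpochSet-class].
#' @param i epoch index.
#' @export
setMethod("[[", "EpochSet", function(x, i) x@epochs[[i]])

#' Subset an EpochSet
#' @param x an [EpochSet-class].
#' @param i indices of epochs to keep.
#' @export
setMethod("[", "EpochSet", function(x, i) {
  qc <- if (nrow(x@qc)) x@qc[i, , drop = FALSE] else x@qc
  new("EpochSet", epochs = x@epochs[i], qc = qc, provenance = x@provenance)
})

setMethod("show", "MmgRecording", function(object) {
  cat(sprintf("MmgRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(object@data), ncol(object@data),
              ncol(object@data) / object@fs, object@fs))
  cat(sprintf("  subject %s, session %s\n", object@subjectId, object@session))
  tab <- table(object@channels$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList: %d events\n", nrow(object@entries)))
  if (nrow(object@entries)) {
    tab <- table(object@entries$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs\n", length(object@epochs)))
  if (length(object@epochs)) {
    e <- object@epochs[[1]]
    cat(sprintf("  window [%g, %g] s, %d channels at %g Hz\n",
                e@window[1], e@window[2], nrow(e@data), e@fs))
  }
  if (nrow(object@qc) && "kept" %in% names(object@qc))
    cat(sprintf("  QC: %d kept / %d total\n", sum(object@qc$kept), nrow(object@qc)))
})

setMethod("show", "SubtrFilter", function(object) {
  cat(sprintf("SubtrFilter: %d targets x %d references x %d frequency bins\n",
              dim(object@W)[1], dim(object@W)[2], dim(object@W)[3]))
})

setMethod("show", "IcaReport", function(object) {
  cat(sprintf("IcaReport: %d components, %d rejected (%.1f%% variance removed)\n",
              object@nComponents, length(object@rejected),
              100 * object@varianceRemoved))
  if (length(object@rejected))
    cat("  rejected:", paste(sprintf("#%d (%s)", object@rejected, object@reasons),
                             collapse = ", "), "\n")
})

setMethod("show", "PsdResult", function(object) {
  cat(sprintf("PsdResult: %d channels, %d bins, %g-%g Hz (df = %g Hz)\n",
              nrow(object@density), length(object@freqs), min(object@freqs),
              max(object@freqs), if (length(object@freqs) > 1)
                object@freqs[2] - object@freqs[1] else NA_real_))
})
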