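# Shared fixtures: small arrays and hand-built epochs, all generated in code.

smallArray <- function(nSensors = 16, nLower = 4, nEdgeRef = 3) {
  makeSensorArray(nSensors, nLower, nEdgeRef)
}

# A session spec with every interference source silenced.
quietSpec <- function(...) {
  sessionSpec(thighLevel = 0, abdomenLevel = 0, cardiacLevel = 0,
              lineLevel = 0, whiteLevel = 0, ...)
}

# Minimal channel table: nLower lower MMG sensors (plus optional extras).
lowerOnlyChannels <- function(n = 2) {
  data.frame(name = sprintf("MMG%03d", seq_len(n)), role = "mmg_lower",
             x = seq_len(n) * 0.01, y = -0.05, z = 0, units = "fT",
             stringsAsFactors = FALSE)
}

# Build an Epoch directly from baseline / signal segments (per channel).
# baseline and signal are channels x samples matrices.
makeEpoch <- function(baseline, signal, fs = 1200, channels = NULL,
                      label = "MK", subjectId = "S01",
                      session = "third_trimester") {
  if (is.null(channels)) channels <- lowerOnlyChannels(nrow(baseline))
  window <- c(-ncol(baseline) / fs, ncol(signal) / fs)
  new("Epoch", data = cbind(baseline, signal), fs = fs, channels = channels,
      label = label, window = window, subjectId = subjectId,
      session = session)
}

# An epoch whose pooled signal/baseline RMS ratio is exactly `ratio`
# (constant baseline 1, constant signal `ratio`), 1 s on each side.
ratioEpoch <- function(ratio, fs = 1200, ...) {
  makeEpoch(matrix(1, 1, fs), matrix(ratio, 1, fs), fs = fs, ...)
}

# Brute-force oracles used in several files.
bruteSlidingRms <- function(x, w, hop) {
  starts <- seq(1, length(x) - w + 1, by = hop)
  vapply(starts, function(s) sqrt(mean(x[s:(s + w - 1)]^2)), numeric(1))
}

bruteSmoothMa <- function(x, nPoints) {
  n <- length(x)
  left <- floor((nPoints - 1) / 2)
  right <- nPoints - 1 - left
  vapply(seq_len(n), function(i) {
    mean(x[max(i - left, 1):min(i + right, n)])
  }, numeric(1))
}
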