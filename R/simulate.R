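#' @include AllClasses.R channels.R utils.R
NULL

#' Construct a BurstSpec
#' @param label exercise label.
#' @param amplitude plateau RMS amplitude on the most exposed channel, fT.
#' @param bandProfile power weights over the 20-80 / 80-140 / 140-200 Hz
#'   bands (non-negative, summing to 1).
#' @param spatialTarget channel role the burst projects onto.
#' @return a validated [BurstSpec-class].
#' @export
burstSpec <- function(label = "MK", amplitude = 80,
                      bandProfile = c(0.5, 0.3, 0.2),
                      spatialTarget = "mmg_lower") {
  new("BurstSpec", label = label, amplitude = amplitude,
      bandProfile = bandProfile, spatialTarget = spatialTarget)
}

#' Construct a SessionSpec
#' @param ... named slots to override; see [SessionSpec-class].
#' @return a validated [SessionSpec-class].
#' @export
sessionSpec <- function(...) new("SessionSpec", ...)

#' Construct an EffectSpec
#' @param ... named slots to override; see [EffectSpec-class].
#' @return a validated [EffectSpec-class].
#' @export
effectSpec <- function(...) new("EffectSpec", ...)

#' Default burst specifications for the five protocol exercises
#'
#' Kegel intensities are ordered SmK < MK < StK (0.5x / 1x / 1.6x the
#' moderate amplitude); abdominal and thigh contractions project onto their
#' EMG electrodes and nearby array regions.
#'
#' @param mkAmplitude plateau RMS of the moderate Kegel, fT.
#' @param mkProfile band power profile of the Kegel bursts.
#' @return named list of [BurstSpec-class], one per label.
#' @export
defaultBursts <- function(mkAmplitude = 80, mkProfile = c(0.5, 0.3, 0.2)) {
  list(
    SmK = burstSpec("SmK", 0.5 * mkAmplitude, mkProfile, "mmg_lower"),
    MK  = burstSpec("MK",  1.0 * mkAmplitude, mkProfile, "mmg_lower"),
    StK = burstSpec("StK", 1.6 * mkAmplitude, mkProfile, "mmg_lower"),
    A   = burstSpec("A",   2.0 * mkAmplitude, c(0.6, 0.3, 0.1), "emg_abdomen"),
    T   = burstSpec("T",   2.5 * mkAmplitude, c(0.6, 0.3, 0.1), "emg_thigh"))
}

# Band edges (Hz) of the three analysis bands.
.bandEdges <- function() list(c(20, 80), c(80, 140), c(140, 200))

# Band-limited unit-RMS Gaussian noise. Zero-phase 6th-order Butterworth
# with edges pulled 3 Hz inside the nominal band, so that essentially all
# synthesised energy falls strictly within the band the weight refers to
# (the half-power points of an exact-edge design would leak ~2-3% outside).
.bandNoise <- function(n, fs, band, margin = 3) {
  edges <- band + c(margin, -margin)
  flt <- signal::butter(6, edges / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n + 2 * fs))[(fs + 1):(fs + n)]
  x / .rmsOf(x)
}

#' Synthesize a band-profiled contraction signal
#'
#' Gaussian noise filtered into the three analysis bands and mixed with
#' amplitude weights `sqrt(bandProfile)`, so the power fractions in the
#' 20-80 / 80-140 / 140-200 Hz bands equal `bandProfile` (up to filter
#' leakage at the shared edges). Unit RMS overall.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param bandProfile power weights (3, non-negative, sum 1).
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return numeric vector of length `n` with RMS 1.
#' @export
burstSignal <- function(n, fs, bandProfile, seed = NULL) {
  gen <- function() {
    x <- numeric(n)
    for (b in seq_along(.bandEdges())) {
      w <- bandProfile[b]
      if (w > 0) x <- x + sqrt(w) * .bandNoise(n, fs, .bandEdges()[[b]])
    }
    if (all(bandProfile == 0)) x else x / .rmsOf(x)
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

# Raised-cosine on/off envelope: rampS ramps at both ends, plateau 1.
.burstEnvelope <- function(n, fs, rampS = 0.5) {
  env <- rep(1, n)
  nr <- min(round(rampS * fs), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[(n - nr + 1):n] <- rev(ramp)
  }
  env
}

#' Spatial projection gains of a source onto all channels
#'
#' MMG sensors receive the source with exponential falloff
#' `exp(-distance / lambda)` from a role-specific target point (below the
#' lower-sensor centroid for pelvic floor sources, abdominal/thigh locations
#' for accessory muscles); the matching EMG electrodes receive gain 1 and
#' the perineal EMG picks up pelvic floor activity at gain 0.8. Gains are
#' normalised so the maximum is 1.
#'
#' @param channels channel metadata data.frame.
#' @param targetRole role the source projects onto.
#' @param lambda falloff length scale, metres.
#' @return numeric gain per channel in `[0, 1]`.
#' @export
projectionGains <- function(channels, targetRole, lambda = 0.05) {
  pos <- as.matrix(channels[, c("x", "y", "z")])
  pt <- switch(targetRole,
    emg_abdomen = c(0, 0.25, 0.05),
    emg_thigh = c(0.165, -0.125, 0),
    emg_perineum = c(0.005, -0.105, 0.02),
    ecg = c(0.05, 0.35, 0.10),
    { # an MMG role: below that role's sensor centroid
      idx <- .roleIdx(channels, targetRole)
      ctr <- if (length(idx)) colMeans(pos[idx, , drop = FALSE]) else c(0, 0, 0)
      ctr + c(0, -0.03, -0.02)
    })
  d <- sqrt(rowSums(sweep(pos, 2, pt)^2))
  g <- exp(-d / lambda)
  isMmg <- channels$role %in% .mmgRoles()
  g[!isMmg] <- 0
  emgMatch <- channels$role == targetRole & !isMmg
  g[emgMatch] <- 1
  if (targetRole == "mmg_lower")
    g[channels$role == "emg_perineum"] <- 0.8
  g[channels$role == "ecg"] <- 0
  if (max(g) > 0) g <- g / max(g)
  g
}

# QRS-like cardiac template sampled at fs: three Gaussians (Q, R, S waves),
# peak amplitude 1.
.cardiacTemplate <- function(fs) {
  t <- seq(-0.1, 0.1, by = 1 / fs)
  -0.3 * exp(-(t + 0.025)^2 / (2 * 0.008^2)) +
    1.0 * exp(-t^2 / (2 * 0.010^2)) -
    0.25 * exp(-(t - 0.030)^2 / (2 * 0.010^2))
}

# Cardiac artifact time series: template repeated at ~bpm with jitter,
# normalised to unit RMS.
.cardiacSeries <- function(n, fs, bpm = 70, jitter = 0.05) {
  x <- numeric(n)
  tpl <- .cardiacTemplate(fs)
  half <- (length(tpl) - 1) / 2
  t <- 0.3
  while (t < n / fs) {
    i0 <- round(t * fs) - half
    idx <- seq(i0, i0 + length(tpl) - 1)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl[ok]
    t <- t + 60 / bpm * (1 + jitter * stats::runif(1, -1, 1))
  }
  if (.rmsOf(x) > 0) x / .rmsOf(x) else x
}

#' Simulate one recording session
#'
#' Renders the full exercise sequence of the protocol: after an initial rest
#' of `restS` seconds, each exercise is a 10 s contraction followed by 10 s
#' of rest -- `nCycles` repetitions each of SmK, MK and StK, then one
#' abdominal (A) and one thigh (T) contraction. Contraction bursts are
#' band-profiled Gaussian noise under a raised-cosine envelope, projected
#' spatially onto the channels named by their [BurstSpec-class]. Thigh and
#' abdominal interference (continuous coloured noise on the array edge and
#' upper sensors), a QRS-like cardiac artifact coupled to all channels and
#' the ECG lead, a 60 Hz line component and white sensor noise are added at
#' the levels in the [SessionSpec-class]. Fully deterministic given `seed`.
#'
#' @param spec a [SessionSpec-class].
#' @param bursts named list of [BurstSpec-class] (one per exercise label);
#'   see [defaultBursts()].
#' @param channels channel layout (default: the full 151-sensor array).
#' @param seed RNG seed (defaults to the spec's seed slot).
#' @param subjectId,session provenance stored in the recording.
#' @return list with elements `recording` ([MmgRecording-class]) and
#'   `events` ([EventList-class]).
#' @examples
#' ses <- simulateSession(sessionSpec(nCycles = 1, fs = 600),
#'                        defaultBursts(), makeSensorArray(30, 6, 4), seed = 7)
#' ses$recording
#' @export
simulateSession <- function(spec = sessionSpec(), bursts = defaultBursts(),
                            channels = makeSensorArray(), seed = spec@seed,
                            subjectId = "S01", session = "third_trimester") {
  validObject(spec)
  for (b in bursts) validObject(b)
  fs <- spec@fs
  labels <- c(rep(c("SmK", "MK", "StK"), each = spec@nCycles), "A", "T")
  labels <- labels[labels %in% names(bursts)]
  cyc <- spec@contractionS + spec@restS
  onsets <- spec@restS + (seq_along(labels) - 1) * cyc
  dur <- spec@restS + length(labels) * cyc
  n <- round(dur * fs)
  ncs <- round(spec@contractionS * fs)
  nch <- nrow(channels)

  withSeed(seed, {
    X <- matrix(0, nch, n)

    # contraction bursts
    env <- .burstEnvelope(ncs, fs)
    for (k in seq_along(labels)) {
      bs <- bursts[[labels[k]]]
      g <- projectionGains(channels, bs@spatialTarget)
      s <- burstSignal(ncs, fs, bs@bandProfile) * env * bs@amplitude
      i0 <- round(onsets[k] * fs)
      X[, (i0 + 1):(i0 + ncs)] <- X[, (i0 + 1):(i0 + ncs)] + outer(g, s)
    }

    # continuous thigh / abdominal interference
    if (spec@thighLevel > 0) {
      gT <- projectionGains(channels, "emg_thigh")
      X <- X + outer(gT * spec@thighLevel, .bandNoise(n, fs, c(20, 150)))
    }
    if (spec@abdomenLevel > 0) {
      gA <- projectionGains(channels, "emg_abdomen")
      X <- X + outer(gA * spec@abdomenLevel, .bandNoise(n, fs, c(20, 100)))
    }

    # cardiac artifact: one template time course on every channel + ECG
    if (spec@cardiacLevel > 0) {
      heart <- .cardiacSeries(n, fs)
      gH <- stats::runif(nch, 0.3, 1) * sample(c(-1, 1), nch, replace = TRUE)
      gH[channels$role == "ecg"] <- 3
      X <- X + outer(gH * spec@cardiacLevel, heart)
    }

    # 60 Hz line noise (common phase, channel-specific amplitude)
    if (spec@lineLevel > 0) {
      tt <- (seq_len(n) - 1) / fs
      line <- sqrt(2) * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
      X <- X + outer(stats::runif(nch, 0.5, 1) * spec@lineLevel, line)
    }

    # broadband sensor noise
    if (spec@whiteLevel > 0)
      X <- X + matrix(stats::rnorm(nch * n, sd = spec@whiteLevel), nch, n)

    rec <- mmgRecording(X, channels, fs = fs, subjectId = subjectId,
                        session = session)
    ev <- eventList(onsets, labels, spec@contractionS)
    list(recording = rec, events = ev)
  })
}
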