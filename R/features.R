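#' @include AllClasses.R utils.R epochs.R
NULL

#' Sliding-window RMS envelope
#'
#' RMS over a sliding window of `windowS` seconds advancing by
#' `windowS - overlapS` seconds. At the protocol values (200 ms window,
#' 199 ms overlap, 1200 Hz) the window is 240 samples and the hop rounds to
#' 1 sample, the closest realizable hop to the nominal 1.2 samples.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param windowS window length in seconds (default 0.2).
#' @param overlapS window overlap in seconds (default 0.199).
#' @return numeric vector of RMS values, one per window position.
#' @export
slidingRms <- function(x, fs, windowS = 0.2, overlapS = 0.199) {
  w <- round(windowS * fs)
  if (length(x) < w) stop("signal shorter than the RMS window")
  hop <- max(1, round((windowS - overlapS) * fs))
  cs <- cumsum(c(0, x^2))
  starts <- seq(1, length(x) - w + 1, by = hop)
  sqrt((cs[starts + w] - cs[starts]) / w)
}

#' Centred moving-average smoothing
#'
#' `nPoints`-point moving average with shrinking windows at the edges, so
#' output length equals input length. Used to smooth the sliding-RMS
#' envelope (protocol value: 100 points).
#'
#' @param x numeric vector.
#' @param nPoints nominal window length (default 100).
#' @return smoothed vector, same length as `x`.
#' @export
smoothMa <- function(x, nPoints = 100) {
  n <- length(x)
  if (!n) return(x)
  left <- floor((nPoints - 1) / 2)
  right <- nPoints - 1 - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1)
  hi <- pmin(i + right, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-tapered segments of `windowS`
#' seconds at `overlap` fractional overlap, mean-detrended per segment,
#' one-sided density normalised so that `sum(density) * df` equals the
#' signal variance (Parseval). At the protocol values (1 s window, 50%
#' overlap) the frequency resolution is 1 Hz.
#'
#' @param x numeric vector, or channels-by-samples matrix.
#' @param fs sampling rate, Hz.
#' @param windowS segment length in seconds (default 1).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return a [PsdResult-class] (density has one row per channel).
#' @export
welchPsd <- function(x, fs, windowS = 1, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- round(windowS * fs)
  if (ncol(x) < n) stop("signal shorter than the Welch window")
  hop <- max(1, round(n * (1 - overlap)))
  win <- .hann(n)
  U <- sum(win^2)
  starts <- seq(1, ncol(x) - n + 1, by = hop)
  nb <- n %/% 2 + 1
  dens <- matrix(0, nrow(x), nb)
  for (ch in seq_len(nrow(x))) {
    acc <- numeric(nb)
    for (s in starts) {
      seg <- x[ch, s:(s + n - 1)]
      seg <- (seg - mean(seg)) * win
      P <- abs(stats::fft(seg)[seq_len(nb)])^2
      acc <- acc + P
    }
    acc <- acc / length(starts) / (fs * U)
    # one-sided: double everything except DC (and Nyquist when n is even)
    sc <- rep(2, nb); sc[1] <- 1
    if (n %% 2 == 0) sc[nb] <- 1
    dens[ch, ] <- acc * sc
  }
  new("PsdResult", freqs = (seq_len(nb) - 1) * fs / n, density = dens,
      params = list(windowS = windowS, overlap = overlap, taper = "hann",
                    fs = fs, nSegments = length(starts)))
}

#' Total power in a band
#'
#' Sum of PSD content (density bins, not integrated by bin width) over the
#' inclusive band `[band[1], band[2]]` Hz, per channel.
#'
#' @param psd a [PsdResult-class].
#' @param band numeric length-2, Hz (default 20-200).
#' @return numeric vector (one value per channel; scalar for one channel).
#' @export
totalPower <- function(psd, band = c(20, 200)) {
  sel <- psd@freqs >= band[1] & psd@freqs <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  p <- rowSums(psd@density[, sel, drop = FALSE])
  if (length(p) == 1) unname(p) else p
}

#' Relative PSD in the three analysis bands
#'
#' Band sums of the density normalised by the total 20-200 Hz power. Bin
#' assignment is half-open at the shared edges -- low `[20, 80)`, middle
#' `[80, 140)`, high `[140, 200]` -- so every bin is counted exactly once
#' and the three fractions sum to 1. For multichannel input the density is
#' averaged across channels first. Zero total power yields `NA`s with a
#' warning.
#'
#' @param psd a [PsdResult-class].
#' @param edges band edges, Hz (default `c(20, 80, 140, 200)`).
#' @return named numeric: `rpsd_L`, `rpsd_M`, `rpsd_H`.
#' @export
rpsdBands <- function(psd, edges = c(20, 80, 140, 200)) {
  d <- colMeans(psd@density)
  f <- psd@freqs
  l <- sum(d[f >= edges[1] & f < edges[2]])
  m <- sum(d[f >= edges[2] & f < edges[3]])
  h <- sum(d[f >= edges[3] & f <= edges[4]])
  tot <- l + m + h
  if (tot <= 0) {
    warning("zero total power: rPSD undefined")
    return(c(rpsd_L = NA_real_, rpsd_M = NA_real_, rpsd_H = NA_real_))
  }
  c(rpsd_L = l / tot, rpsd_M = m / tot, rpsd_H = h / tot)
}

#' Extract amplitude and spectral features from one epoch
#'
#' Computes, on the signal interval of a baseline-corrected moderate-Kegel
#' epoch and averaged over the `mmg_lower` channels: the mean of the
#' smoothed sliding-RMS envelope (`rms_fT`), total 20-200 Hz Welch power
#' (`total_power`, density summed over bins), the relative PSD band
#' fractions, and the epoch SNR.
#'
#' @param epoch a baseline-corrected [Epoch-class].
#' @param config a [PipelineConfig-class] supplying all analysis scalars.
#' @param channelRoles channels to average over (default `mmg_lower`).
#' @param reduce how to reduce the smoothed RMS envelope to a scalar:
#'   its mean (default) or its max.
#' @return one-row data.frame: subject, session, label, rms_fT,
#'   total_power, rpsd_L, rpsd_M, rpsd_H, snr_db.
#' @export
epochFeatures <- function(epoch, config = pipelineConfig(),
                          channelRoles = "mmg_lower",
                          reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  idx <- .roleIdx(epoch@channels, channelRoles)
  if (!length(idx)) stop("no channels with role(s): ",
                         paste(channelRoles, collapse = ", "))
  fs <- epoch@fs
  sig <- epoch@data[idx, .signalCols(epoch), drop = FALSE]
  rmsPerCh <- vapply(seq_along(idx), function(i) {
    env <- smoothMa(slidingRms(sig[i, ], fs, config@rmsWindowS,
                               config@rmsOverlapS), config@smoothPoints)
    if (reduce == "mean") mean(env) else max(env)
  }, numeric(1))
  psd <- welchPsd(sig, fs, config@welchWindowS, config@welchOverlap)
  meanDens <- new("PsdResult", freqs = psd@freqs,
                  density = matrix(colMeans(psd@density), 1),
                  params = psd@params)
  tp <- totalPower(meanDens, band = config@bandEdges[c(1, 4)])
  rp <- rpsdBands(meanDens, edges = config@bandEdges)
  data.frame(subject = epoch@subjectId, session = epoch@session,
             label = epoch@label, rms_fT = mean(rmsPerCh),
             total_power = tp, rpsd_L = unname(rp[1]),
             rpsd_M = unname(rp[2]), rpsd_H = unname(rp[3]),
             snr_db = epochSnrDb(epoch, channelRoles),
             stringsAsFactors = FALSE)
}

#' Feature table for a whole epoch set
#'
#' Applies [epochFeatures()] to every epoch and binds the rows, adding an
#' epoch index column.
#'
#' @param epochSet an [EpochSet-class] of baseline-corrected epochs.
#' @param config a [PipelineConfig-class].
#' @param ... passed to [epochFeatures()].
#' @return data.frame, one row per epoch.
#' @export
epochSetFeatures <- function(epochSet, config = pipelineConfig(), ...) {
  if (!length(epochSet@epochs))
    return(data.frame(subject = character(), session = character(),
                      label = character(), epoch = integer(),
                      rms_fT = numeric(), total_power = numeric(),
                      rpsd_L = numeric(), rpsd_M = numeric(),
                      rpsd_H = numeric(), snr_db = numeric()))
  rows <- lapply(seq_along(epochSet@epochs), function(i) {
    df <- epochFeatures(epochSet@epochs[[i]], config, ...)
    cbind(df[, 1:3, drop = FALSE], epoch = i, df[, -(1:3), drop = FALSE])
  })
  do.call(rbind, rows)
}

#' Per-sensor power map
#'
#' Total 20-200 Hz Welch power per MMG sensor over an analysed interval --
#' the spatial power topography over the array. For an [Epoch-class] the
#' signal interval is analysed; for an [MmgRecording-class] the whole
#' recording (or a sample range).
#'
#' @param x an [Epoch-class] or [MmgRecording-class].
#' @param config a [PipelineConfig-class].
#' @param sampleRange optional length-2 sample range (recordings only).
#' @return data.frame: name, role, x, y, z, power (one row per MMG sensor).
#' @export
powerMap <- function(x, config = pipelineConfig(), sampleRange = NULL) {
  ch <- x@channels
  idx <- .roleIdx(ch, .mmgRoles())
  dat <- if (is(x, "Epoch")) x@data[idx, .signalCols(x), drop = FALSE]
  else {
    d <- x@data[idx, , drop = FALSE]
    if (!is.null(sampleRange)) d[, sampleRange[1]:sampleRange[2], drop = FALSE]
    else d
  }
  psd <- welchPsd(dat, x@fs, config@welchWindowS, config@welchOverlap)
  pw <- totalPower(psd, band = config@bandEdges[c(1, 4)])
  data.frame(name = ch$name[idx], role = ch$role[idx],
             x = ch$x[idx], y = ch$y[idx], z = ch$z[idx],
             power = as.numeric(pw), stringsAsFactors = FALSE)
}
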