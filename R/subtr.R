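#' @include AllClasses.R utils.R
NULL

## STFT helpers (Hann analysis window, weighted overlap-add reconstruction).

# Frame start indices for a signal of length len.
.stftStarts <- function(len, n, hop) {
  if (len < n) stop("signal shorter than the STFT window")
  seq(1, len - n + 1, by = hop)
}

# STFT of one channel: complex matrix, (n/2 + 1) bins x frames.
.stft <- function(x, n, hop, win) {
  starts <- .stftStarts(length(x), n, hop)
  frames <- vapply(starts, function(s) x[s:(s + n - 1)] * win,
                   numeric(n))
  F <- stats::mvfft(frames)
  F[seq_len(n %/% 2 + 1), , drop = FALSE]
}

# Rebuild full Hermitian spectra (n bins) from one-sided bins.
.fullSpectrum <- function(half, n) {
  nb <- nrow(half)
  rbind(half, Conj(half[(nb - 1):2, , drop = FALSE]))
}

#' Fit a frequency-dependent subtraction (SUBTR) filter
#'
#' For every STFT frequency bin, estimates the complex regression of each
#' target channel on the reference channels (cross-spectral density times
#' the regularised inverse of the reference auto-spectral matrix), yielding
#' the coefficients that best predict reference-coherent interference in
#' the target channels. Hann window, 50% hop, diagonal loading
#' `loading x mean reference power` for numerical stability.
#'
#' @param recording an [MmgRecording-class].
#' @param referenceRoles channel roles used as references (default the
#'   edge sensors closest to the thighs).
#' @param targetRoles channel roles to clean; default: all MMG channels
#'   not serving as references.
#' @param windowS STFT window length in seconds (default 1).
#' @param loading diagonal loading factor (default 1e-3).
#' @return a [SubtrFilter-class].
#' @export
fitSubtr <- function(recording, referenceRoles = "mmg_edge_reference",
                     targetRoles = NULL, windowS = 1, loading = 1e-3) {
  ch <- recording@channels
  fs <- recording@fs
  refIdx <- .roleIdx(ch, referenceRoles)
  if (!length(refIdx)) stop("no reference channels with role(s): ",
                            paste(referenceRoles, collapse = ", "))
  if (is.null(targetRoles)) targetRoles <- setdiff(.mmgRoles(), referenceRoles)
  tgtIdx <- setdiff(.roleIdx(ch, targetRoles), refIdx)
  if (!length(tgtIdx)) stop("no target channels to clean")
  n <- round(windowS * fs)
  if (ncol(recording@data) < 10 * n)
    stop("recording must be at least 10 STFT windows long")
  hop <- n %/% 2
  win <- .hann(n)

  Fref <- lapply(refIdx, function(i) .stft(recording@data[i, ], n, hop, win))
  Ftgt <- lapply(tgtIdx, function(i) .stft(recording@data[i, ], n, hop, win))
  nb <- n %/% 2 + 1
  K <- ncol(Fref[[1]])
  nR <- length(refIdx); nT <- length(tgtIdx)

  W <- array(complex(real = 0), dim = c(nT, nR, nb))
  for (b in seq_len(nb)) {
    R <- t(vapply(Fref, function(F) F[b, ], complex(K)))   # nR x K
    Tm <- t(vapply(Ftgt, function(F) F[b, ], complex(K)))  # nT x K
    if (nR == 1) R <- matrix(R, nrow = 1)
    if (nT == 1) Tm <- matrix(Tm, nrow = 1)
    G <- (R %*% Conj(t(R))) / K
    C <- (Tm %*% Conj(t(R))) / K
    lam <- loading * mean(Re(diag(G)))
    if (!is.finite(lam) || lam <= 0) lam <- loading
    W[, , b] <- C %*% solve(G + diag(lam, nR))
  }
  new("SubtrFilter", W = W, freqs = (seq_len(nb) - 1) * fs / n,
      windowLength = n, hop = hop,
      targetNames = ch$name[tgtIdx], refNames = ch$name[refIdx], fs = fs)
}

#' Apply a SUBTR filter to a recording
#'
#' Predicts the reference-coherent component of every target channel in the
#' STFT domain (per-bin multiplication by the fitted coefficients),
#' reconstructs it by weighted overlap-add, and subtracts it from the
#' target channels. Reference and non-target channels pass through
#' unchanged; output length equals input length. With all-zero reference
#' data the output equals the input exactly.
#'
#' @param recording an [MmgRecording-class] with the same channel set and
#'   sampling rate the filter was fitted on.
#' @param filt a [SubtrFilter-class].
#' @return a cleaned [MmgRecording-class].
#' @export
applySubtr <- function(recording, filt) {
  ch <- recording@channels
  if (recording@fs != filt@fs) stop("sampling rate differs from the fit")
  refIdx <- match(filt@refNames, ch$name)
  tgtIdx <- match(filt@targetNames, ch$name)
  if (anyNA(refIdx) || anyNA(tgtIdx))
    stop("recording channels do not match the fitted filter")
  n <- filt@windowLength; hop <- filt@hop
  win <- .hann(n)
  nb <- n %/% 2 + 1
  nT <- length(tgtIdx); nR <- length(refIdx)
  nsamp <- ncol(recording@data)

  pad <- n
  padded <- function(x) c(numeric(pad), x, numeric(pad))
  L <- nsamp + 2 * pad
  starts <- .stftStarts(L, n, hop)
  K <- length(starts)

  # one-sided reference spectra, nR x nb x K
  Rspec <- array(complex(real = 0), c(nR, nb, K))
  for (r in seq_len(nR))
    Rspec[r, , ] <- .stft(padded(recording@data[refIdx[r], ]), n, hop, win)

  num <- matrix(0, nT, L)
  den <- numeric(L)
  win2 <- win^2
  for (k in seq_len(K)) {
    # predicted interference spectrum of every target at frame k
    I <- matrix(complex(real = 0), nT, nb)
    for (r in seq_len(nR)) {
      Wr <- matrix(filt@W[, r, ], nT, nb)
      I <- I + Wr * matrix(Rspec[r, , k], nT, nb, byrow = TRUE)
    }
    full <- .fullSpectrum(t(I), n)                 # n x nT
    frames <- Re(stats::mvfft(full, inverse = TRUE)) / n
    idx <- starts[k]:(starts[k] + n - 1)
    num[, idx] <- num[, idx] + t(frames) * matrix(win, nT, n, byrow = TRUE)
    den[idx] <- den[idx] + win2
  }
  den[den < 1e-12] <- 1
  interf <- sweep(num, 2, den, "/")[, (pad + 1):(pad + nsamp), drop = FALSE]

  out <- recording@data
  out[tgtIdx, ] <- out[tgtIdx, , drop = FALSE] - interf
  initialize(recording, data = out)
}

#' Remove the cardiac artifact from EMG channels
#'
#' Applies the SUBTR filter with the maternal ECG lead as the sole
#' reference and the surface-EMG channels as targets, removing
#' ECG-coherent power from the EMG recordings.
#'
#' @param recording an [MmgRecording-class] containing an ECG channel and
#'   at least one EMG channel.
#' @param windowS,loading passed to [fitSubtr()].
#' @return the recording with cleaned EMG channels.
#' @export
removeCardiacEmg <- function(recording, windowS = 1, loading = 1e-3) {
  ch <- recording@channels
  if (!length(.roleIdx(ch, "ecg"))) stop("no ECG channel in recording")
  if (!length(.roleIdx(ch, .emgRoles()))) stop("no EMG channels in recording")
  filt <- fitSubtr(recording, referenceRoles = "ecg",
                   targetRoles = .emgRoles(), windowS = windowS,
                   loading = loading)
  applySubtr(recording, filt)
}
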