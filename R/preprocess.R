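#' @include AllClasses.R utils.R
NULL

# 2nd-order IIR notch biquad (standard RBJ design), coefficients (b, a).
.notchCoef <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a recording
#'
#' 4th-order Butterworth band-pass (default 20-200 Hz) plus a 60 Hz notch
#' (2nd-order IIR, Q = 30), both applied forward-backward (zero phase), so
#' the effective magnitude response is the squared design response and
#' epoch-locked amplitude analysis suffers no phase distortion. All channels
#' are filtered; length and channel order are preserved.
#'
#' @param recording an [MmgRecording-class].
#' @param low,high band edges in Hz.
#' @param order Butterworth order (per edge).
#' @param notch notch frequency in Hz; `NA` disables the notch.
#' @param notchQ notch quality factor.
#' @return a filtered [MmgRecording-class].
#' @export
bandpassNotch <- function(recording, low = 20, high = 200, order = 4,
                          notch = 60, notchQ = 30) {
  fs <- recording@fs
  if (low <= 0) stop("low cutoff must be > 0")
  if (high >= fs / 2) stop("high cutoff must be below Nyquist (fs/2)")
  bp <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  nc <- if (is.finite(notch) && !is.na(notch)) .notchCoef(notch, fs, notchQ)
        else NULL
  X <- recording@data
  for (i in seq_len(nrow(X))) {
    y <- signal::filtfilt(bp, X[i, ])
    if (!is.null(nc)) y <- signal::filtfilt(nc$b, nc$a, y)
    X[i, ] <- y
  }
  initialize(recording, data = X)
}

#' Magnitude response of the zero-phase band-pass + notch chain
#'
#' The designed gain at frequency `f` after forward-backward application
#' (i.e. the squared single-pass magnitude). Used to verify measured
#' passband gains against the design.
#'
#' @param f frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @param low,high,order,notch,notchQ as in [bandpassNotch()].
#' @return numeric gain per frequency.
#' @export
filterGain <- function(f, fs, low = 20, high = 200, order = 4,
                       notch = 60, notchQ = 30) {
  bp <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(1i * 2 * pi * f / fs)
  hOf <- function(b, a) {
    num <- vapply(z, function(zz) sum(b * zz^(-(seq_along(b) - 1))), complex(1))
    den <- vapply(z, function(zz) sum(a * zz^(-(seq_along(a) - 1))), complex(1))
    abs(num / den)
  }
  g <- hOf(bp$b, bp$a)^2
  if (is.finite(notch) && !is.na(notch)) {
    nc <- .notchCoef(notch, fs, notchQ)
    g <- g * hOf(nc$b, nc$a)^2
  }
  g
}

#' ICA-based denoising of the MMG channels
#'
#' Decomposes the MMG channels with fixed-point negentropy-maximising ICA
#' (FastICA, seeded initialisation), then rejects components whose time
#' course correlates with the ECG channel above `corrThreshold` (absolute
#' Pearson) or whose mixing weights concentrate more than `concThreshold`
#' of their energy on the edge-reference sensors, and reconstructs the data
#' without them. Non-MMG channels pass through unchanged.
#'
#' @param recording an [MmgRecording-class] containing an ECG channel.
#' @param corrThreshold ECG-correlation rejection threshold (default 0.8).
#' @param concThreshold edge-concentration rejection threshold (default 0.8).
#' @param nComponents number of components; by default the number of
#'   covariance eigenvalues above 1.5x the white-noise floor (mean of the
#'   lower half of the spectrum), capped at 40 -- restricting the
#'   decomposition to the structured subspace, where the fixed-point
#'   iteration is well conditioned. Rejected components are subtracted from
#'   the data, so signal outside this subspace is never altered.
#' @param seed seed for the random orthogonal initialisation.
#' @param maxRetries re-initialisations attempted on non-convergence.
#' @param tol fixed-point convergence tolerance.
#' @param decim temporal decimation factor used when estimating the
#'   unmixing matrix (the estimated projection is then applied to the full
#'   data); `NULL` picks the smallest factor keeping about 40000 samples.
#' @return list with `recording` (denoised) and `report`
#'   ([IcaReport-class]).
#' @export
icaDenoise <- function(recording, corrThreshold = 0.8, concThreshold = 0.8,
                       nComponents = NULL, seed = 1, maxRetries = 3,
                       decim = NULL, tol = 1e-4) {
  ch <- recording@channels
  mmgIdx <- .roleIdx(ch, .mmgRoles())
  ecgIdx <- .roleIdx(ch, "ecg")
  if (length(mmgIdx) < 2) stop("ICA requires at least 2 MMG channels")
  if (!length(ecgIdx)) stop("no ECG channel in recording")
  X <- t(recording@data[mmgIdx, , drop = FALSE])   # samples x channels
  ecg <- recording@data[ecgIdx[1], ]
  if (is.null(decim)) decim <- max(1L, ceiling(nrow(X) / 40000))
  Xfit <- X[seq(1, nrow(X), by = decim), , drop = FALSE]
  nc <- if (is.null(nComponents)) {
    # structured subspace: eigenvalues above the white-noise floor
    # (mean of the lower half of the spectrum)
    ev <- eigen(stats::cov(Xfit), symmetric = TRUE, only.values = TRUE)$values
    floorVar <- mean(ev[(length(ev) %/% 2):length(ev)])
    min(max(2L, sum(ev > 1.5 * floorVar)), 40L, length(mmgIdx))
  } else nComponents

  # retry non-convergent fits with a fresh seeded rotation; from the second
  # retry on, also shrink the component count -- the weakest "structured"
  # component is typically the one that keeps the symmetric iteration from
  # stabilising
  fit <- NULL
  for (attempt in 0:maxRetries) {
    ncTry <- max(2L, nc - max(0L, attempt - 1L))
    Rmat <- withSeed(seed + attempt, {
      qr.Q(qr(matrix(stats::rnorm(ncTry * ncTry), ncTry, ncTry)))
    })
    fit <- ica::icafast(Xfit, nc = ncTry, Rmat = Rmat, maxit = 500, tol = tol)
    if (isTRUE(fit$converged)) { nc <- ncTry; break }
  }
  if (!isTRUE(fit$converged))
    stop("ICA failed to converge after ", maxRetries + 1, " initialisations")

  # project full-length data onto the estimated components
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- Xc %*% t(fit$W)

  edgeRows <- which(ch$role[mmgIdx] == "mmg_edge_reference")
  rejected <- integer(); reasons <- character()
  for (j in seq_len(nc)) {
    r <- suppressWarnings(abs(stats::cor(S[, j], ecg)))
    if (is.finite(r) && r > corrThreshold) {
      rejected <- c(rejected, j); reasons <- c(reasons, "ecg_correlated")
      next
    }
    if (length(edgeRows)) {
      conc <- sum(fit$M[edgeRows, j]^2) / sum(fit$M[, j]^2)
      if (is.finite(conc) && conc > concThreshold) {
        rejected <- c(rejected, j); reasons <- c(reasons, "reference_concentrated")
      }
    }
  }

  # subtract the rejected components; signal outside the nc-dimensional
  # subspace is untouched, and with nothing rejected output equals input
  varAll <- sum(Xc^2)
  if (length(rejected)) {
    Xrej <- S[, rejected, drop = FALSE] %*% t(fit$M[, rejected, drop = FALSE])
    Xclean <- X - Xrej
    varRem <- sum(Xrej^2) / varAll
  } else {
    Xclean <- X
    varRem <- 0
  }

  out <- recording@data
  out[mmgIdx, ] <- t(Xclean)
  report <- new("IcaReport", nComponents = nc, rejected = rejected,
                reasons = reasons, varianceRemoved = varRem)
  if (length(rejected))
    .log("ICA rejected %d/%d components (%s)", length(rejected), nc,
         paste(unique(reasons), collapse = ", "))
  list(recording = initialize(recording, data = out), report = report)
}
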