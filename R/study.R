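#' @include AllClasses.R simulate.R
NULL

# Shift a band profile additively on (L, M), letting H absorb the remainder;
# errors if the shift drives any weight outside [0, 1].
.shiftProfile <- function(w, dL, dM) {
  w2 <- c(w[1] + dL, w[2] + dM, w[3] - dL - dM)
  if (any(w2 < -1e-9) || any(w2 > 1 + 1e-9))
    stop("effect drives band weights outside [0, 1]")
  pmin(pmax(w2, 0), 1) / sum(pmin(pmax(w2, 0), 1))
}

# Between-subject jitter of a band profile: same shift structure, but a rare
# draw falling outside the simplex is clipped and renormalised rather than
# refused (it is sampling variation, not a user-specified effect).
.jitterProfile <- function(w, dL, dM) {
  w2 <- pmax(c(w[1] + dL, w[2] + dM, w[3] - dL - dM), 0.005)
  w2 / sum(w2)
}

#' Draw per-subject ground-truth parameters for a paired study
#'
#' Each subject's third-trimester moderate-Kegel amplitude is drawn
#' log-normally around `baseAmplitude` (log-SD `effect@sdBetweenRms`) and
#' their band profile around `baseProfile` (additive Gaussian on the low and
#' middle weights, SD `effect@sdBetweenBand`, high band absorbing).
#' Postpartum parameters apply the [EffectSpec-class] shifts: amplitude
#' multiplied by `rmsRatio`, low/middle weights shifted by `dRpsdL`/`dRpsdM`.
#'
#' @param nSubjects number of subjects (the study analysed 9 complete pairs).
#' @param effect an [EffectSpec-class].
#' @param baseAmplitude cohort-mean MK amplitude, fT.
#' @param baseProfile cohort-mean band power profile.
#' @param seed RNG seed; subject draws use `seed + subject index`.
#' @return data.frame with columns subject, session, amplitude_fT,
#'   w_L, w_M, w_H (one row per subject per session).
#' @export
drawStudyParameters <- function(nSubjects, effect = effectSpec(),
                                baseAmplitude = 80,
                                baseProfile = c(0.5, 0.3, 0.2),
                                seed = 1) {
  if (nSubjects < 2) stop("nSubjects must be >= 2")
  validObject(effect)
  rows <- lapply(seq_len(nSubjects), function(i) {
    withSeed(seed + i, {
      amp <- baseAmplitude * exp(stats::rnorm(1, 0, effect@sdBetweenRms))
      dl <- stats::rnorm(1, 0, effect@sdBetweenBand)
      dm <- stats::rnorm(1, 0, effect@sdBetweenBand)
      wPre <- .jitterProfile(baseProfile, dl, dm)
      wPost <- .shiftProfile(wPre, effect@dRpsdL, effect@dRpsdM)
      data.frame(
        subject = sprintf("S%02d", i),
        session = sessionLabels(),
        amplitude_fT = c(amp, amp * effect@rmsRatio),
        w_L = c(wPre[1], wPost[1]), w_M = c(wPre[2], wPost[2]),
        w_H = c(wPre[3], wPost[3]), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Simulate a full paired pregnancy/postpartum study with rendered signals
#'
#' Draws per-subject ground-truth parameters with [drawStudyParameters()]
#' and renders one [simulateSession()] recording per subject per session,
#' optionally writing each as a recording bundle.
#'
#' @param nSubjects number of subjects.
#' @param spec a [SessionSpec-class] shared by all sessions.
#' @param effect an [EffectSpec-class].
#' @param channels channel layout (default: full 151-sensor array).
#' @param baseAmplitude,baseProfile cohort-level MK burst parameters.
#' @param seed master seed; per-session seeds are derived from it.
#' @param dir if non-NULL, bundles are written to
#'   `dir/<subject>_<session>/` and paths returned instead of objects.
#' @return list with `truth` (the ground-truth parameter table) and
#'   `sessions` (named list of `list(recording, events)` or bundle paths).
#' @export
simulatePairedStudy <- function(nSubjects = 9, spec = sessionSpec(),
                                effect = effectSpec(),
                                channels = makeSensorArray(),
                                baseAmplitude = 80,
                                baseProfile = c(0.5, 0.3, 0.2),
                                seed = 1, dir = NULL) {
  truth <- drawStudyParameters(nSubjects, effect, baseAmplitude,
                               baseProfile, seed)
  sessions <- list()
  for (r in seq_len(nrow(truth))) {
    subj <- truth$subject[r]
    sess <- truth$session[r]
    bursts <- defaultBursts(mkAmplitude = truth$amplitude_fT[r],
                            mkProfile = c(truth$w_L[r], truth$w_M[r],
                                          truth$w_H[r]))
    sseed <- seed + 1000L * r
    ses <- simulateSession(spec, bursts, channels, seed = sseed,
                           subjectId = subj, session = sess)
    key <- paste(subj, sess, sep = "_")
    if (is.null(dir)) {
      sessions[[key]] <- ses
    } else {
      p <- file.path(dir, key)
      writeRecording(ses$recording, ses$events, p)
      sessions[[key]] <- p
    }
  }
  list(truth = truth, sessions = sessions)
}

#' Simulate an epoch-level feature table directly from the parameter model
#'
#' The fast, signal-free counterpart of rendering and re-analysing full
#' sessions: per-subject ground truth is drawn as in
#' [drawStudyParameters()], and each kept moderate-Kegel epoch observes that
#' truth under epoch-to-epoch measurement noise (multiplicative log-normal
#' on RMS with coefficient of variation `rmsCv`; additive Gaussian with SD
#' `bandSd` on the band weights, renormalised). Total power scales as the
#' squared RMS. Used for statistical calibration of the paired comparison
#' at study scale.
#'
#' @param nSubjects subjects per study.
#' @param nEpochs kept MK epochs per session.
#' @param effect an [EffectSpec-class].
#' @param baseAmplitude,baseProfile cohort-level parameters.
#' @param rmsCv epoch-level coefficient of variation of RMS (default 0.15).
#' @param bandSd epoch-level SD of each band weight (default 0.02).
#' @param seed RNG seed.
#' @return feature data.frame: subject, session, label, epoch, rms_fT,
#'   total_power, rpsd_L, rpsd_M, rpsd_H, snr_db.
#' @export
simulateFeatureTable <- function(nSubjects = 9, nEpochs = 3,
                                 effect = effectSpec(),
                                 baseAmplitude = 80,
                                 baseProfile = c(0.5, 0.3, 0.2),
                                 rmsCv = 0.15, bandSd = 0.02, seed = 1) {
  truth <- drawStudyParameters(nSubjects, effect, baseAmplitude,
                               baseProfile, seed)
  sdlog <- sqrt(log(1 + rmsCv^2))
  withSeed(seed + 99991L, {
    rows <- lapply(seq_len(nrow(truth)), function(r) {
      rms <- truth$amplitude_fT[r] * exp(stats::rnorm(nEpochs, 0, sdlog))
      w <- matrix(rep(c(truth$w_L[r], truth$w_M[r], truth$w_H[r]),
                      each = nEpochs), nEpochs, 3)
      w <- w + matrix(stats::rnorm(3 * nEpochs, 0, bandSd), nEpochs, 3)
      w <- pmax(w, 0)
      w <- w / rowSums(w)
      data.frame(
        subject = truth$subject[r], session = truth$session[r],
        label = "MK", epoch = seq_len(nEpochs),
        rms_fT = rms, total_power = rms^2 / 100,
        rpsd_L = w[, 1], rpsd_M = w[, 2], rpsd_H = w[, 3],
        snr_db = 20, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
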