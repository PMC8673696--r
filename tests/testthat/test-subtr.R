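# Frequency-dependent reference subtraction.

fs <- 1200

twoChannel <- function(target, ref) {
  ch <- data.frame(name = c("T1", "R1"),
                   role = c("mmg_lower", "mmg_edge_reference"),
                   x = c(0, 0.1), y = c(-0.05, 0.1), z = 0, units = "fT",
                   stringsAsFactors = FALSE)
  mmgRecording(rbind(target, ref), ch, fs = fs)
}

dB <- function(p) 10 * log10(p)

test_that("constant coupling is recovered at every occupied bin", {
  set.seed(1)
  r <- rnorm(60 * fs)
  rec <- twoChannel(0.5 * r, r)
  filt <- fitSubtr(rec)
  # skip DC and Nyquist edges; everything else carries reference power
  bins <- which(filt@freqs >= 5 & filt@freqs <= 590)
  expect_true(all(abs(Mod(filt@W[1, 1, bins]) - 0.5) < 0.01))
})

test_that("subtraction removes coherent power without touching the signal", {
  set.seed(2)
  n <- 120 * fs
  r <- rnorm(n)                         # strong interference source
  s <- 0.15 * rnorm(n)                  # weak uncorrelated muscle signal
  rec <- twoChannel(s + 0.5 * r, r)
  filt <- fitSubtr(rec)
  cleaned <- applySubtr(rec, filt)
  resid <- signalData(cleaned)[1, ] - s
  reduction <- dB(mean((0.5 * r)^2) / mean(resid^2))
  expect_gt(reduction, 20)
  distortion <- abs(dB(mean(signalData(cleaned)[1, ]^2) / mean(s^2)))
  expect_lt(distortion, 1)
  # output length preserved, reference channel untouched
  expect_equal(ncol(signalData(cleaned)), n)
  expect_identical(signalData(cleaned)[2, ], signalData(rec)[2, ])
})

test_that("zero reference data makes subtraction the identity", {
  set.seed(3)
  s <- rnorm(30 * fs)
  recFit <- twoChannel(s + 0.5 * rnorm(30 * fs), rnorm(30 * fs))
  filt <- fitSubtr(recFit)
  rec0 <- twoChannel(s, numeric(30 * fs))
  out <- applySubtr(rec0, filt)
  expect_equal(signalData(out)[1, ], s, tolerance = 1e-12)
})

test_that("frequency-dependent coupling is resolved per bin", {
  set.seed(4)
  n <- 120 * fs
  r <- rnorm(n)
  lowF <- signal::butter(6, 100 / (fs / 2), type = "low")
  highF <- signal::butter(6, 100 / (fs / 2), type = "high")
  target <- 0.8 * signal::filtfilt(lowF, r) + 0.2 * signal::filtfilt(highF, r)
  filt <- fitSubtr(twoChannel(target, r))
  # plateau bins well clear of the 100 Hz transition
  lowBins <- which(filt@freqs >= 30 & filt@freqs <= 70)
  highBins <- which(filt@freqs >= 150 & filt@freqs <= 400)
  expect_true(all(abs(Mod(filt@W[1, 1, lowBins]) - 0.8) < 0.08))
  expect_true(all(abs(Mod(filt@W[1, 1, highBins]) - 0.2) < 0.02))
})

test_that("a second pass changes target power by at most 1 dB", {
  set.seed(5)
  n <- 120 * fs
  r <- rnorm(n)
  rec <- twoChannel(0.15 * rnorm(n) + 0.5 * r, r)
  once <- applySubtr(rec, fitSubtr(rec))
  twice <- applySubtr(once, fitSubtr(once))
  change <- abs(dB(mean(signalData(twice)[1, ]^2) /
                     mean(signalData(once)[1, ]^2)))
  expect_lt(change, 1)
})

test_that("STFT subtraction matches time-domain least squares on constant coupling", {
  set.seed(6)
  n <- 120 * fs
  r <- rnorm(n)
  s <- 0.15 * rnorm(n)
  t <- s + 0.5 * r
  rec <- twoChannel(t, r)
  cleaned <- applySubtr(rec, fitSubtr(rec))
  beta <- sum(t * r) / sum(r^2)
  oracle <- t - beta * r
  expect_equal(mean(signalData(cleaned)[1, ]^2), mean(oracle^2),
               tolerance = 0.01)
})

test_that("ECG-referenced subtraction cleans EMG channels only", {
  set.seed(7)
  n <- 60 * fs
  ch <- data.frame(
    name = c("MMG001", "EMGper1", "EMGper2", "ECG1"),
    role = c("mmg_lower", "emg_perineum", "emg_perineum", "ecg"),
    x = 0, y = c(-0.05, -0.10, -0.11, 0.35), z = 0,
    units = c("fT", "uV", "uV", "uV"), stringsAsFactors = FALSE)
  ecg <- mmglam:::.cardiacSeries(n, fs)
  muscle1 <- 0.1 * rnorm(n); muscle2 <- 0.1 * rnorm(n)
  mmg <- rnorm(n)
  X <- rbind(mmg, muscle1 + 0.3 * ecg, muscle2, 3 * ecg + 0.05 * rnorm(n))
  rec <- mmgRecording(X, ch, fs = fs)
  out <- removeCardiacEmg(rec)
  resid <- signalData(out)[2, ] - muscle1
  expect_gt(dB(mean((0.3 * ecg)^2) / mean(resid^2)), 20)
  # EMG without cardiac content barely changes
  change <- abs(dB(mean(signalData(out)[3, ]^2) / mean(muscle2^2)))
  expect_lt(change, 1)
  # MMG channel untouched
  expect_identical(signalData(out)[1, ], signalData(rec)[1, ])

  noEmg <- mmgRecording(X[c(1, 4), ], ch[c(1, 4), ], fs = fs)
  expect_error(removeCardiacEmg(noEmg), "EMG")
  noEcg <- mmgRecording(X[1:3, ], ch[1:3, ], fs = fs)
  expect_error(removeCardiacEmg(noEcg), "ECG")
})
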