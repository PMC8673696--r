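# Band-pass/notch filtering and ICA denoising.

fs <- 1200

toneRecording <- function(freq, nSec = 30, fs. = fs) {
  ch <- lowerOnlyChannels(1)
  t <- (seq_len(nSec * fs.) - 1) / fs.
  mmgRecording(matrix(sin(2 * pi * freq * t), 1), ch, fs = fs.)
}

midRms <- function(rec) {
  x <- signalData(rec)[1, ]
  n <- length(x)
  sqrt(mean(x[round(n / 4):round(3 * n / 4)]^2))
}

test_that("passband tones pass at the designed gain", {
  out <- bandpassNotch(toneRecording(100))
  measured <- midRms(out) * sqrt(2)      # RMS -> amplitude
  designed <- filterGain(100, fs)
  expect_equal(measured, designed, tolerance = 0.002)
  expect_equal(measured, 1, tolerance = 0.02)
})

test_that("the 60 Hz notch attenuates line noise by at least 30 dB", {
  out <- bandpassNotch(toneRecording(60))
  atten <- -20 * log10(midRms(out) * sqrt(2))
  expect_gt(atten, 30)
})

test_that("stopband content and DC are strongly attenuated", {
  out <- bandpassNotch(toneRecording(5))
  expect_lt(midRms(out) * sqrt(2), 0.05)
  out2 <- bandpassNotch(toneRecording(350))
  expect_lt(midRms(out2) * sqrt(2), 0.05)
})

test_that("filtering is zero-phase and shape-preserving", {
  ch <- lowerOnlyChannels(1)
  n <- 12000
  x <- numeric(n); k <- 6000; x[k] <- 1
  out <- bandpassNotch(mmgRecording(matrix(x, 1), ch, fs = fs))
  y <- signalData(out)[1, ]
  centroid <- sum(seq_len(n) * y^2) / sum(y^2)
  expect_lt(abs(centroid - k), 1)
  expect_equal(ncol(signalData(out)), n)

  zero <- bandpassNotch(mmgRecording(matrix(0, 1, n), ch, fs = fs))
  expect_equal(max(abs(signalData(zero))), 0)

  expect_error(bandpassNotch(toneRecording(10), high = 700), "Nyquist")
})

test_that("ICA removes a planted cardiac component", {
  ch <- smallArray(30, 6, 4)
  spec <- sessionSpec(nCycles = 1, thighLevel = 0, abdomenLevel = 0,
                      cardiacLevel = 40, lineLevel = 0, whiteLevel = 10)
  ses <- simulateSession(spec, defaultBursts(), ch, seed = 11)
  rec <- ses$recording
  res <- icaDenoise(rec, seed = 2, nComponents = 6)
  expect_gte(length(res$report@rejected), 1)
  expect_true("ecg_correlated" %in% res$report@reasons)

  heart <- signalData(rec)[channelInfo(rec)$role == "ecg", ]
  idx <- which(channelInfo(rec)$role == "mmg_other")
  corBefore <- mean(abs(apply(signalData(rec)[idx, ], 1, cor, heart)))
  corAfter <- mean(abs(apply(signalData(res$recording)[idx, ], 1, cor, heart)))
  expect_lt(corAfter, 0.2 * corBefore)
})

test_that("ICA with nothing rejected reproduces the input", {
  ch <- smallArray(12, 3, 2)
  ses <- simulateSession(sessionSpec(nCycles = 1), defaultBursts(), ch,
                         seed = 13)
  res <- icaDenoise(ses$recording, corrThreshold = 1.0, concThreshold = 1.0,
                    seed = 3)
  expect_equal(length(res$report@rejected), 0)
  expect_equal(signalData(res$recording), signalData(ses$recording),
               tolerance = 1e-6)
})

test_that("ICA is deterministic under a fixed seed and rejects edge-locked sources", {
  ch <- smallArray(20, 4, 4)
  ses <- simulateSession(sessionSpec(nCycles = 1), defaultBursts(), ch,
                         seed = 17)
  a <- icaDenoise(ses$recording, seed = 4)
  b <- icaDenoise(ses$recording, seed = 4)
  expect_identical(a$report@rejected, b$report@rejected)
  expect_identical(signalData(a$recording), signalData(b$recording))

  # an intermittent source living only on the edge sensors is flagged as
  # reference-concentrated
  edge <- which(ch$role == "mmg_edge_reference")
  n <- 60 * fs
  X <- matrix(rnorm(nrow(ch) * n, sd = 1), nrow(ch), n)
  env <- rep(rep(c(1, 0), each = 5 * fs), length.out = n)
  src <- burstSignal(n, fs, c(1, 0, 0), seed = 8) * env * 50
  for (i in edge) X[i, ] <- X[i, ] + src * runif(1, 0.8, 1.2)
  rec <- mmgRecording(X, ch, fs = fs)
  res <- icaDenoise(rec, seed = 5, nComponents = 2)
  expect_true("reference_concentrated" %in% res$report@reasons)
})
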