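# Sliding RMS, smoothing, Welch PSD, band powers, epoch features, power maps.

fs <- 1200

test_that("sliding RMS matches closed forms and the brute-force oracle", {
  out <- slidingRms(rep(3, 1000), fs)
  expect_true(all(out == 3))

  t <- (seq_len(12 * 240) - 1) / fs          # windows span integer cycles
  out2 <- slidingRms(sin(2 * pi * 100 * t), fs)
  expect_true(all(abs(out2 - 1 / sqrt(2)) < 1e-3))

  set.seed(1)
  x <- rnorm(fs)
  expect_equal(slidingRms(x, fs), bruteSlidingRms(x, 240, 1),
               tolerance = 1e-12)
  expect_error(slidingRms(rnorm(100), fs), "shorter")
})

test_that("moving-average smoothing matches its oracle and edge behaviour", {
  expect_equal(smoothMa(rep(2.5, 500)), rep(2.5, 500))

  alt <- rep(c(1, -1), 250)
  sm <- smoothMa(alt, 100)
  expect_true(all(abs(sm[100:400]) < 1e-12))

  set.seed(2)
  x <- rnorm(777)
  expect_equal(smoothMa(x, 100), bruteSmoothMa(x, 100), tolerance = 1e-12)
  expect_equal(smoothMa(x, 7), bruteSmoothMa(x, 7), tolerance = 1e-12)
  expect_equal(length(smoothMa(x, 100)), length(x))
})

test_that("Welch PSD satisfies Parseval and locates spectral peaks", {
  set.seed(3)
  x <- rnorm(60 * fs, sd = 3)
  psd <- welchPsd(x, fs)
  df <- psd@freqs[2] - psd@freqs[1]
  expect_equal(df, 1)
  expect_equal(sum(psd@density) * df, 9, tolerance = 0.1)

  t <- (seq_len(10 * fs) - 1) / fs
  psd2 <- welchPsd(sin(2 * pi * 100 * t), fs)
  expect_equal(psd2@freqs[which.max(psd2@density[1, ])], 100)

  psd0 <- welchPsd(numeric(2 * fs), fs)
  expect_equal(max(psd0@density), 0)
})

test_that("total power counts density bins inclusively", {
  nb <- 601
  flat <- new("PsdResult", freqs = 0:600, density = matrix(1, 1, nb),
              params = list())
  expect_equal(totalPower(flat), 181)  # bins 20..200 inclusive at 1 Hz
  zero <- new("PsdResult", freqs = 0:600, density = matrix(0, 1, nb),
              params = list())
  expect_equal(totalPower(zero), 0)
  set.seed(4)
  d <- matrix(abs(rnorm(nb)), 1)
  psd <- new("PsdResult", freqs = 0:600, density = d, params = list())
  expect_equal(totalPower(psd), sum(d[1, 21:201]), tolerance = 1e-12)
  expect_error(totalPower(psd, band = c(601, 700)), "band")
})

test_that("relative PSD uses half-open band edges and sums to one", {
  nb <- 601
  flat <- new("PsdResult", freqs = 0:600, density = matrix(1, 1, nb),
              params = list())
  rp <- rpsdBands(flat)
  expect_equal(unname(rp), c(60, 60, 61) / 181, tolerance = 1e-12)

  conc <- matrix(0, 1, nb); conc[101] <- 5  # all power at 100 Hz
  rp2 <- rpsdBands(new("PsdResult", freqs = 0:600, density = conc,
                       params = list()))
  expect_equal(unname(rp2), c(0, 1, 0))

  set.seed(5)
  d <- matrix(abs(rnorm(nb)), 1)
  rp3 <- rpsdBands(new("PsdResult", freqs = 0:600, density = d,
                       params = list()))
  expect_equal(sum(rp3), 1, tolerance = 1e-9)

  zero <- new("PsdResult", freqs = 0:600, density = matrix(0, 1, nb),
              params = list())
  expect_warning(rpz <- rpsdBands(zero), "undefined")
  expect_true(all(is.na(rpz)))
})

test_that("epoch features recover generator band profiles and scale correctly", {
  prof <- c(0.2, 0.6, 0.2)
  sig <- matrix(burstSignal(12000, fs, prof, seed = 6) * 50, 1)
  base <- matrix(rnorm(3600, sd = 1e-6), 1)
  e <- makeEpoch(base, sig, fs = fs)
  f <- epochFeatures(e)
  expect_lt(max(abs(c(f$rpsd_L, f$rpsd_M, f$rpsd_H) - prof)), 0.05)
  expect_equal(f$rms_fT, 50, tolerance = 0.05)

  s <- 3
  e2 <- makeEpoch(s * base, s * sig, fs = fs)
  f2 <- epochFeatures(e2)
  expect_equal(f2$rms_fT, s * f$rms_fT, tolerance = 1e-9)
  expect_equal(f2$total_power, s^2 * f$total_power, tolerance = 1e-9)
  expect_equal(c(f2$rpsd_L, f2$rpsd_M, f2$rpsd_H),
               c(f$rpsd_L, f$rpsd_M, f$rpsd_H), tolerance = 1e-9)
})

test_that("degenerate zero-signal epochs are reported as missing", {
  e <- makeEpoch(matrix(rnorm(3600, sd = 1), 1), matrix(0, 1, 12000), fs = fs)
  f <- suppressWarnings(epochFeatures(e))
  expect_equal(f$rms_fT, 0)
  expect_true(is.na(f$rpsd_L))
})

test_that("power maps localise bursts and scale quadratically", {
  ch <- smallArray(30, 6, 4)
  ses <- simulateSession(quietSpec(nCycles = 1), defaultBursts()["MK"], ch,
                         seed = 8)
  eps <- extractEpochs(ses$recording, ses$events, labels = "MK")
  pm <- powerMap(eps[[1]])
  expect_equal(nrow(pm), 30)
  expect_identical(pm$role[which.max(pm$power)], "mmg_lower")

  rec2 <- mmgRecording(2 * signalData(ses$recording), channelInfo(ses$recording))
  eps2 <- extractEpochs(rec2, ses$events, labels = "MK")
  pm2 <- powerMap(eps2[[1]])
  expect_equal(pm2$power, 4 * pm$power, tolerance = 1e-9)

  zrec <- mmgRecording(matrix(0, nrow(ch), 20 * fs), ch)
  zpm <- powerMap(zrec)
  expect_equal(max(zpm$power), 0)
})
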