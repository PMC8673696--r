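test_that("sensor array construction is deterministic with correct role counts", {
  ch <- makeSensorArray(151, 20, 12)
  expect_equal(nrow(ch), 158)  # 151 MMG + 6 EMG + 1 ECG
  expect_equal(sum(ch$role == "mmg_lower"), 20)
  expect_equal(sum(ch$role == "mmg_edge_reference"), 12)
  expect_equal(sum(ch$role %in% c("mmg_lower", "mmg_other",
                                  "mmg_edge_reference")), 151)
  expect_equal(sum(ch$role == "ecg"), 1)
  expect_identical(ch, makeSensorArray(151, 20, 12))
  # lower sensors really are the lowest rows of the cap
  expect_true(max(ch$y[ch$role == "mmg_lower"]) <
                stats::median(ch$y[ch$role == "mmg_other"]))

  ch0 <- makeSensorArray(151, 0, 0)
  expect_true(all(ch0$role[1:151] == "mmg_other"))
  expect_error(makeSensorArray(10, 8, 8), "exceed")
})

test_that("sessions are reproducible and follow the exercise schedule", {
  ch <- smallArray()
  spec <- sessionSpec(nCycles = 2)
  a <- simulateSession(spec, defaultBursts(), ch, seed = 5)
  b <- simulateSession(spec, defaultBursts(), ch, seed = 5)
  expect_identical(signalData(a$recording), signalData(b$recording))
  expect_identical(eventTable(a$events), eventTable(b$events))

  ev <- eventTable(a$events)
  cyc <- spec@contractionS + spec@restS
  expect_equal(ev$onset_s, spec@restS + (seq_len(nrow(ev)) - 1) * cyc)
  expect_equal(ev$label, c("SmK", "SmK", "MK", "MK", "StK", "StK", "A", "T"))
  expect_true(all(ev$duration_s == spec@contractionS))
  c2 <- simulateSession(spec, defaultBursts(), ch, seed = 6)
  expect_false(identical(signalData(a$recording), signalData(c2$recording)))
})

test_that("noise-free bursts land at the specified amplitude and stay silent at rest", {
  ch <- smallArray(30, 6, 4)
  amp <- 80
  s0 <- simulateSession(quietSpec(nCycles = 1),
                        defaultBursts(mkAmplitude = amp)["MK"], ch, seed = 3)
  rec <- s0$recording
  fs <- samplingRate(rec)
  onset <- eventTable(s0$events)$onset_s[1]
  g <- projectionGains(ch, "mmg_lower")
  best <- which.max(g * (channelInfo(rec)$role == "mmg_lower"))
  plateau <- signalData(rec)[best, round((onset + 1.2) * fs):round((onset + 8.8) * fs)]
  expect_equal(sqrt(mean(plateau^2)), amp * g[best], tolerance = 0.02)
  rest <- signalData(rec)[best, 1:round(0.9 * onset * fs)]
  expect_equal(max(abs(rest)), 0)
})

test_that("burst band profiles are realised in the spectrum", {
  # pure middle-band burst: nearly all 20-200 Hz power inside 80-140 Hz
  x <- burstSignal(12000, 1200, c(0, 1, 0), seed = 9)
  psd <- welchPsd(x, 1200)
  rp <- rpsdBands(psd)
  expect_gt(rp["rpsd_M"], 0.99)
  # generic profile recovered within Welch estimation error
  prof <- c(0.2, 0.6, 0.2)
  x2 <- burstSignal(12000, 1200, prof, seed = 10)
  rp2 <- rpsdBands(welchPsd(x2, 1200))
  expect_lt(max(abs(rp2 - prof)), 0.05)
})

test_that("paired study ground truth carries the injected effect", {
  nullTruth <- drawStudyParameters(9, effectSpec(rmsRatio = 1, dRpsdL = 0,
                                                 dRpsdM = 0), seed = 2)
  pre <- nullTruth[nullTruth$session == "third_trimester", ]
  post <- nullTruth[nullTruth$session == "postpartum", ]
  expect_equal(pre$amplitude_fT, post$amplitude_fT)
  expect_equal(pre$w_L, post$w_L)

  truth <- drawStudyParameters(9, effectSpec(rmsRatio = 0.75,
                                             dRpsdL = -0.10, dRpsdM = 0.10),
                               seed = 2)
  pre <- truth[truth$session == "third_trimester", ]
  post <- truth[truth$session == "postpartum", ]
  expect_equal(post$amplitude_fT, 0.75 * pre$amplitude_fT)
  expect_equal(post$w_L, pre$w_L - 0.10)
  expect_equal(post$w_M, pre$w_M + 0.10)
  expect_equal(rowSums(cbind(post$w_L, post$w_M, post$w_H)), rep(1, 9))
  # an effect that would push weights out of [0, 1] is refused
  expect_error(drawStudyParameters(5, effectSpec(dRpsdL = -0.9, dRpsdM = 0),
                                   seed = 1), "outside")
})

test_that("simulatePairedStudy renders both sessions per subject", {
  ch <- smallArray(10, 3, 2)
  study <- simulatePairedStudy(2, sessionSpec(nCycles = 1), effectSpec(),
                               channels = ch, seed = 4)
  expect_equal(nrow(study$truth), 4)
  expect_setequal(names(study$sessions),
                  c("S01_third_trimester", "S01_postpartum",
                    "S02_third_trimester", "S02_postpartum"))
  rec <- study$sessions[["S01_postpartum"]]$recording
  expect_s4_class(rec, "MmgRecording")
  expect_identical(sessionOf(rec), "postpartum")
})

test_that("epoch-level feature tables follow the parameter model", {
  ft <- simulateFeatureTable(9, 3, effectSpec(), seed = 7)
  expect_equal(nrow(ft), 9 * 2 * 3)
  expect_equal(ft$rpsd_L + ft$rpsd_M + ft$rpsd_H, rep(1, nrow(ft)))
  expect_identical(ft, simulateFeatureTable(9, 3, effectSpec(), seed = 7))
  # grand means reflect the injected postpartum amplitude drop
  ga <- grandAverage(ft)
  pre <- ga[ga$session == "third_trimester", "rms_fT"]
  post <- ga[ga$session == "postpartum", "rms_fT"]
  expect_gt(mean(pre), mean(post))
})
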