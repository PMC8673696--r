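# Epoch extraction, baseline correction, SNR, and the quality gate.

test_that("epochs are cut to round(13 x fs) samples around each trigger", {
  ch <- lowerOnlyChannels(2)
  fs <- 1200
  rec <- mmgRecording(matrix(rnorm(2 * 100 * fs), 2), ch, fs = fs)
  ev <- eventList(c(10, 30, 50), c("MK", "MK", "MK"))
  eps <- extractEpochs(rec, ev, labels = "MK")
  expect_equal(length(eps), 3)
  for (i in 1:3) expect_equal(ncol(signalData(eps[[i]])), 15600)
  # trigger sample is the first sample of the signal interval
  e <- eps[[1]]
  expect_identical(signalData(e)[, 3601], signalData(rec)[, 10 * fs + 1])
})

test_that("events too close to the edges are dropped with a warning", {
  ch <- lowerOnlyChannels(1)
  rec <- mmgRecording(matrix(0, 1, 1200 * 30), ch)
  ev <- eventList(c(1, 15), c("MK", "MK"))
  expect_warning(eps <- extractEpochs(rec, ev, labels = "MK"), "dropped")
  expect_equal(length(eps), 1)
  expect_equal(eps@provenance$nDropped, 1)
  expect_equal(eps@provenance$nEventsSelected, 2)

  none <- extractEpochs(rec, ev, labels = "SmK")
  expect_s4_class(none, "EpochSet")
  expect_equal(length(none), 0)
})

test_that("baseline correction zeroes the pre-trigger mean per channel", {
  e <- makeEpoch(matrix(5, 2, 1200), matrix(5, 2, 1200))
  out <- baselineCorrect(e)
  expect_equal(max(abs(signalData(out))), 0)

  e2 <- makeEpoch(matrix(0, 1, 1200), matrix(3, 1, 1200))
  expect_identical(signalData(baselineCorrect(e2)), signalData(e2))

  set.seed(1)
  e3 <- makeEpoch(matrix(rnorm(2 * 1200, mean = 2), 2),
                  matrix(rnorm(2 * 1200, mean = 7), 2))
  out3 <- baselineCorrect(e3)
  blMeans <- rowMeans(signalData(out3)[, 1:1200])
  expect_true(all(abs(blMeans) <= 1e-12 * apply(signalData(out3), 1, sd)))
})

test_that("SNR follows its closed form", {
  expect_equal(epochSnrDb(ratioEpoch(1)), 0)
  expect_equal(epochSnrDb(ratioEpoch(10)), 20)
  expect_equal(epochSnrDb(ratioEpoch(10^(1 / 20))), 1)
  expect_warning(s <- epochSnrDb(makeEpoch(matrix(0, 1, 1200),
                                           matrix(1, 1, 1200))), "capped")
  expect_equal(s, 300)
})

test_that("SNR is scale-invariant and monotone in signal amplitude", {
  set.seed(2)
  for (rep in 1:5) {
    base <- matrix(rnorm(2 * 1200), 2)
    sig <- matrix(rnorm(2 * 1200), 2)
    e <- makeEpoch(base, sig)
    s0 <- epochSnrDb(e)
    sScaled <- epochSnrDb(makeEpoch(3.7 * base, 3.7 * sig))
    expect_equal(sScaled, s0, tolerance = 1e-12)
    amps <- c(0.5, 1, 2, 5)
    snrs <- vapply(amps, function(a)
      epochSnrDb(makeEpoch(base, a * sig)), numeric(1))
    expect_true(all(diff(snrs) > 0))
  }
})

test_that("the quality gate discards strictly-below-threshold epochs only", {
  eps <- new("EpochSet", epochs = list(
    ratioEpoch(10^(0.5 / 20)), ratioEpoch(10^(1.0 / 20)),
    ratioEpoch(10^(1.5 / 20))))
  qc <- qcFilter(eps, thresholdDb = 1)
  expect_equal(qc$report$kept, c(FALSE, TRUE, TRUE))
  expect_equal(length(qc$kept), 2)
  expect_equal(qc$report$snr_db, c(0.5, 1.0, 1.5), tolerance = 1e-9)
  # count conservation
  expect_equal(sum(qc$report$kept) + sum(!qc$report$kept), length(eps))

  all3 <- qcFilter(eps, thresholdDb = -Inf)
  expect_equal(length(all3$kept), 3)
})

test_that("a session with no surviving epochs flags the subject for exclusion", {
  good <- lapply(1:3, function(i) ratioEpoch(10, subjectId = "S07"))
  badPost <- lapply(1:3, function(i)
    ratioEpoch(10^(0.2 / 20), subjectId = "S07", session = "postpartum"))
  eps <- new("EpochSet", epochs = c(good, badPost))
  qc <- suppressMessages(qcFilter(eps, thresholdDb = 1))
  expect_equal(nrow(qc$excludedSubjects), 1)
  expect_equal(qc$excludedSubjects$subject, "S07")
  expect_equal(qc$excludedSubjects$session, "postpartum")
})
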