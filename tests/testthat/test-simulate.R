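test_that("beat times follow the programmed rate exactly without jitter", {
  b <- makeBeatTimes(60, 10, jitterCv = 0)
  expect_length(b, 11)             # beats at 0..10 s
  expect_equal(diff(b), rep(1, 10), tolerance = 1e-12)
  b2 <- makeBeatTimes(120, 60, jitterCv = 0)
  expect_equal(60 / mean(diff(b2)), 120, tolerance = 1e-9)
  expect_error(makeBeatTimes(-5, 10), "non-positive")
  expect_error(makeBeatTimes(60, 0), "duration")
})

test_that("RR jitter has the requested coefficient of variation", {
  b <- makeBeatTimes(75, 300, seed = 21L, jitterCv = 0.02)
  gaps <- diff(b)
  cv <- sd(gaps) / mean(gaps)
  expect_gt(cv, 0.005)
  expect_lt(cv, 0.04)
  # deterministic under the seed
  expect_identical(b, makeBeatTimes(75, 300, seed = 21L, jitterCv = 0.02))
})

test_that("synthetic ECG places R peaks at the beat times", {
  beats <- seq(0, 30, by = 1)   # 60 bpm
  ecg <- simulateEcg(beats, 30, noiseSd = 0)
  x <- signalValues(ecg)[, 1]
  fs <- nominalRate(ecg)
  # peak sample within one ECG sample of each beat
  for (tb in beats[2:30]) {
    i <- round(tb * fs) + 1
    win <- (i - 20):(i + 20)
    expect_lte(abs(which.max(x[win]) + win[1] - 1 - i), 1)
  }
  # amplitude scaling doubles peak height, leaves peak times unchanged
  ecg2 <- simulateEcg(beats, 30, noiseSd = 0, amplitude = 2)
  i1 <- which.max(x)
  i2 <- which.max(signalValues(ecg2)[, 1])
  expect_equal(i1, i2)
  expect_equal(max(signalValues(ecg2)[, 1]), 2 * max(x), tolerance = 1e-9)
})

test_that("a beat-free ECG is flat noise without spurious spikes", {
  for (seed in 1:3) {
    ecg <- simulateEcg(numeric(0), 30, seed = seed, noiseSd = 0.02)
    x <- signalValues(ecg)[, 1]
    expect_lt(max(abs(x)), 5 * 0.02)
  }
})

test_that("still-posture motion concentrates spectral energy in the
           cardiac band at high SNR", {
  spec <- conditionSpec(posture = "sitting", physicalState = "relaxed",
                        durationS = 60, hrBpm = 75, snrDb = 40, seed = 8L)
  beats <- makeBeatTimes(75, 60, seed = 1L, jitterCv = 0)
  motion <- simulateMotion(beats, spec, drift = FALSE)
  # spectral oracle: Fourier band power on a resampled uniform grid
  rs <- resampleCubic(motion, 256)
  for (ch in c(1, 4)) {
    v <- signalValues(rs)[, ch]
    sp <- stats::spec.pgram(v - mean(v), taper = 0, plot = FALSE)
    f <- sp$freq * 256
    inBand <- sum(sp$spec[f >= 8 & f <= 32])
    expect_gt(inBand / sum(sp$spec), 0.7)
  }
})

test_that("gait harmonics dominate when the cardiac component is silenced", {
  spec <- conditionSpec(posture = "standing", physicalState = "aroused",
                        speedKmh = 8.5, durationS = 60, hrBpm = 150,
                        seed = 9L)
  beats <- makeBeatTimes(150, 60, seed = 2L, jitterCv = 0)
  motion <- simulateMotion(beats, spec, cardiacGain = 0)
  rs <- resampleCubic(motion, 64)
  v <- signalValues(rs)[, 1]
  sp <- stats::spec.pgram(v - mean(v), taper = 0, plot = FALSE)
  f <- sp$freq * 64
  fPeak <- f[which.max(sp$spec)]
  expect_lt(abs(fPeak - 2.8), 0.1)   # step frequency at 8.5 km/h
})

test_that("motion rendering is deterministic and SNR-monotone", {
  spec <- conditionSpec(durationS = 30, hrBpm = 80, seed = 4L)
  beats <- makeBeatTimes(80, 30, seed = 3L)
  m1 <- simulateMotion(beats, spec)
  m2 <- simulateMotion(beats, spec)
  expect_identical(signalValues(m1), signalValues(m2))
  expect_identical(timestamps(m1), timestamps(m2))

  # cardiac-band power ratio grows with snrDb
  bandRatio <- function(snr) {
    sp2 <- spec
    sp2@snrDb <- snr
    rs <- resampleCubic(simulateMotion(beats, sp2), 256)
    v <- signalValues(rs)[, 1]
    pg <- stats::spec.pgram(v - mean(v), taper = 0, plot = FALSE)
    f <- pg$freq * 256
    sum(pg$spec[f >= 8 & f <= 32]) / sum(pg$spec)
  }
  ratios <- vapply(c(-10, 0, 10, 20), bandRatio, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("sessions share beats between motion and ECG and cover the
           duration", {
  spec <- conditionSpec(durationS = 40, hrBpm = c(60, 180),
                        hrTime = c(0, 40), seed = 6L)
  ses <- simulateSession(spec)
  expect_gte(max(timestamps(ses@motion)), 40)
  expect_gte(max(timestamps(ses@ecg)), 40)
  expect_true(nominalRate(ses@motion) >= 100 &&
              nominalRate(ses@motion) <= 200)
  expect_equal(nominalRate(ses@ecg), 512)
  # instantaneous rate tracks the ramp
  localHr <- 60 / diff(ses@trueBeatTimes)
  mids <- (head(ses@trueBeatTimes, -1) + tail(ses@trueBeatTimes, -1)) / 2
  expected <- approx(c(0, 40), c(60, 180), xout = mids, rule = 2)$y
  expect_lt(max(abs(localHr - expected) / expected), 0.12)

  # two seeds: different noise, identical condition tags
  sesB <- simulateSession(conditionSpec(durationS = 40, hrBpm = 90,
                                        seed = 60L))
  sesC <- simulateSession(conditionSpec(durationS = 40, hrBpm = 90,
                                        seed = 61L))
  expect_false(identical(signalValues(sesB@motion),
                         signalValues(sesC@motion)))
  mB <- recordingMeta(sesB@motion)
  mC <- recordingMeta(sesC@motion)
  expect_identical(mB[c("posture", "physicalState", "speedKmh")],
                   mC[c("posture", "physicalState", "speedKmh")])
})

test_that("condition grid covers the 12 protocol conditions", {
  specs <- standardConditions(durationS = 30, seed = 2L)
  expect_length(specs, 12)
  postures <- vapply(specs, function(s) s@posture, character(1))
  states <- vapply(specs, function(s) s@physicalState, character(1))
  speeds <- vapply(specs, function(s) s@speedKmh, numeric(1))
  expect_equal(sum(speeds == 0), 6)
  expect_setequal(speeds[speeds > 0], c(3.2, 4.5, 5.8, 6.4, 8.5, 10.3))
  expect_setequal(paste(postures[speeds == 0], states[speeds == 0]),
                  as.vector(outer(c("sitting", "standing", "supine"),
                                  c("relaxed", "aroused"), paste)))
  expect_error(conditionSpec(speedKmh = 7.7), "unknown speed")
  expect_error(conditionSpec(posture = "sitting", speedKmh = 3.2),
               "standing")
})
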