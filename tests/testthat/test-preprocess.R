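test_that("cubic resampling interpolates nodes and polynomials exactly", {
  # already-uniform input at the target rate is reproduced at shared points
  ts <- seq(0, 2, by = 1 / 256)
  vals <- matrix(rnorm(length(ts) * 2), ncol = 2)
  rec <- multichannelRecording(ts, vals, nominalRate = 256)
  rs <- resampleCubic(rec, 256)
  expect_equal(signalValues(rs), vals, tolerance = 1e-9)

  # a cubic polynomial sampled at 100 Hz resamples exactly ("fmm" spline)
  ts2 <- seq(0, 3, by = 0.01)
  poly <- function(t) 2 - t + 0.5 * t^2 - 0.25 * t^3
  rec2 <- multichannelRecording(ts2, matrix(poly(ts2), ncol = 1))
  rs2 <- resampleCubic(rec2, 256)
  expected <- poly(timestamps(rs2))
  expect_lt(max(abs(signalValues(rs2)[, 1] - expected) /
                pmax(abs(expected), 1e-6)), 1e-6)

  expect_error(resampleCubic(multichannelRecording(0:2 / 10,
                                                   matrix(1:3, ncol = 1)),
                             256), "at least 4")
})

test_that("Savitzky-Golay trend reproduces low-order polynomials", {
  # constants are reproduced exactly everywhere, including edges
  expect_equal(sgTrend(rep(3.5, 100)), rep(3.5, 100), tolerance = 1e-12)
  # a global quadratic is inside the model space of every window fit
  x <- seq_len(200)
  quad <- 1 + 0.3 * x - 0.002 * x^2
  expect_lt(max(abs(sgTrend(quad) - quad) / abs(quad)), 1e-9)
  expect_error(sgTrend(rnorm(100), window = 30L), "odd")
  expect_error(sgTrend(rnorm(100), order = 5L, window = 5L), "odd|order")
  expect_error(sgTrend(rnorm(10)), "shorter")
})

test_that("Savitzky-Golay trend equals per-window least squares", {
  # independent oracle: explicit lm fit over each (truncated) window
  sgOracle <- function(x, order, window) {
    n <- length(x)
    m <- (window - 1) / 2
    vapply(seq_len(n), function(i) {
      idx <- max(1, i - m):min(n, i + m)
      fit <- lm(y ~ poly(d, order, raw = TRUE),
                data = data.frame(y = x[idx], d = idx - i))
      unname(coef(fit)[1])
    }, numeric(1))
  }
  set.seed(11)
  x <- rnorm(120) + sin(seq_len(120) / 10)
  expect_equal(sgTrend(x, 2L, 31L), sgOracle(x, 2, 31), tolerance = 1e-9)
  expect_equal(sgTrend(x, 3L, 21L), sgOracle(x, 3, 21), tolerance = 1e-9)
})

test_that("trend smooths noise", {
  set.seed(5)
  x <- rnorm(2000)
  expect_lt(var(sgTrend(x)), var(x))
})

test_that("motion removal is linear and preserves embedded pulses", {
  expect_equal(removeMotion(rep(2, 100)), rep(0, 100), tolerance = 1e-12)
  set.seed(6)
  x <- rnorm(300)
  expect_equal(removeMotion(3 * x), 3 * removeMotion(x), tolerance = 1e-9)
  # quadratic drift + fast pulse train: residual correlates with the pulses
  t <- seq(0, 5, by = 1 / 256)
  drift <- 5 + 2 * t - 0.5 * t^2
  pulse <- sin(2 * pi * 20 * t) * rep(c(1, 0), length.out = length(t))
  resid <- removeMotion(drift + pulse)
  expect_gt(cor(resid, pulse), 0.9)
})

test_that("z-normalization follows the population convention", {
  expect_equal(zNormalize(c(0, 2)), c(-1, 1))
  set.seed(7)
  x <- rnorm(500, mean = 3, sd = 4)
  z <- zNormalize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(mean(z^2) - 1), 1e-6)
  expect_equal(zNormalize(z), z, tolerance = 1e-9)   # idempotent
  expect_error(zNormalize(rep(1, 10), channel = "acc_x"), "acc_x")
})

test_that("window counts follow floor((T - window)/stride) + 1", {
  ses <- cached("ses180", function()
    simulateSession(conditionSpec(durationS = 180, hrBpm = 80, seed = 2L)))
  ws <- windowize(ses)
  expect_equal(recordingMeta(ws)$nCandidates, 176)
  expect_equal(dim(ws@windows)[2:3], c(6L, 1280L))
  # exactly one window from a 5 s span
  ses5 <- simulateSession(conditionSpec(durationS = 5, hrBpm = 120,
                                        physicalState = "aroused",
                                        seed = 3L))
  expect_equal(recordingMeta(windowize(ses5))$nCandidates, 1)
  # too short errors
  ses3 <- simulateSession(conditionSpec(durationS = 3.5, hrBpm = 120,
                                        physicalState = "aroused",
                                        seed = 3L))
  expect_error(windowize(ses3), "shorter than the window")
})

test_that("labels outside 60-200 bpm are excluded", {
  fast <- simulateSession(conditionSpec(durationS = 60, hrBpm = 210,
                                        physicalState = "aroused",
                                        seed = 13L))
  ws <- windowize(fast)
  expect_equal(nWindows(ws), 0L)
  expect_equal(recordingMeta(ws)$nExcluded,
               recordingMeta(ws)$nCandidates)
  slow <- simulateSession(conditionSpec(durationS = 60, hrBpm = 45,
                                        seed = 14L))
  expect_equal(nWindows(windowize(slow)), 0L)
})

test_that("windows are per-channel normalized and labels match the
           programmed rate", {
  ses <- quietSession(hr = 96, durationS = 40, seed = 15L)
  ws <- windowize(ses)
  expect_gt(nWindows(ws), 30)
  expect_lt(max(abs(hrLabels(ws) - 96)), 1)
  w <- getWindow(ws, 3)$data
  expect_equal(dim(w), c(6L, 1280L))
  for (ch in 1:6) {
    expect_lt(abs(mean(w[ch, ])), 1e-9)
    expect_lt(abs(mean(w[ch, ]^2) - 1), 1e-6)
  }
})

test_that("pooled datasets retain provenance from every condition", {
  sessions <- cached("gridSessions", function()
    lapply(standardConditions(durationS = 12, seed = 5L),
           simulateSession))
  ds <- buildDataset(sessions, shuffleSeed = 9L)
  conds <- unique(ds@source$condition)
  expect_gte(length(conds), 8)   # all represented unless excluded by HR
  expect_true(all(!is.na(splitTags(ds))))
  ds2 <- buildDataset(sessions, shuffleSeed = 9L)
  expect_identical(splitTags(ds), splitTags(ds2))
})
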