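test_that("relative accuracy matches hand-computed cases", {
  expect_equal(hrAccuracy(c(100, 120), c(100, 120)), 100)
  expect_equal(hrAccuracy(100, 90), 90)
  expect_equal(hrAccuracy(c(100, 200), c(110, 180)), 90)
  # scale invariance under joint positive rescaling
  set.seed(1)
  y <- runif(50, 60, 180)
  p <- y + rnorm(50, sd = 5)
  expect_equal(hrAccuracy(y, p), hrAccuracy(2 * y, 2 * p))
  expect_error(hrAccuracy(c(100, 0), c(90, 10)), "positive")
  expect_error(hrAccuracy(1:3, 1:4), "length")
})

test_that("error metrics match definitions and invariants", {
  r <- errorMetrics(c(100, 110), c(103, 107))  # d = [3, -3]
  expect_equal(r@mae, 3)
  expect_equal(r@sdae, 0)
  expect_equal(r@rmse, 3)
  r2 <- errorMetrics(c(100, 110), c(100, 114)) # d = [0, 4]
  expect_equal(r2@mae, 2)
  expect_equal(r2@rmse, sqrt(8))
  expect_gte(r2@rmse, r2@mae)
  y <- c(80, 100, 120)
  r3 <- errorMetrics(y, y)
  expect_equal(r3@mae, 0)
  expect_equal(r3@rmse, 0)
  expect_equal(r3@cc, 1)
  expect_equal(r3@accuracyPct, 100)
  # rmse >= mae on random inputs (Jensen)
  set.seed(2)
  for (i in 1:20) {
    yy <- runif(30, 60, 180)
    pp <- yy + rnorm(30, sd = 8)
    rr <- errorMetrics(yy, pp)
    expect_gte(rr@rmse, rr@mae)
  }
  # undefined correlation reported as NA, not a number
  expect_warning(rz <- errorMetrics(c(100, 100), c(90, 95)), "zero variance")
  expect_true(is.na(rz@cc))
})

test_that("Bland-Altman limits use the population SD convention", {
  b <- blandAltman(c(100, 100, 100), c(101, 101, 101))
  expect_equal(b@meanDiff, 1)
  expect_equal(b@sdDiff, 0)
  expect_equal(c(b@loaLow, b@loaHigh), c(1, 1))
  b2 <- blandAltman(c(100, 100), c(99, 101))   # diffs [-1, 1]
  expect_equal(b2@meanDiff, 0)
  expect_equal(b2@sdDiff, 1)
  expect_equal(c(b2@loaLow, b2@loaHigh), c(-1.96, 1.96))
  expect_equal(b2@pairs$mean, c(99.5, 100.5))
  expect_error(blandAltman(100, 90), "2 pairs")
})

test_that("stratified folds deal sorted runs evenly", {
  labels <- 1:10
  folds <- stratifiedFolds(labels, 2L, seed = 1L)
  # each fold receives exactly one of each consecutive pair
  for (pair in list(1:2, 3:4, 5:6, 7:8, 9:10))
    expect_setequal(folds[pair], 1:2)
  expect_lt(max(abs(tapply(labels, folds, mean) - mean(labels))), 0.51)
  # singleton folds at z = n
  expect_setequal(stratifiedFolds(1:6, 6L, seed = 2L), 1:6)
  # reproducible under a fixed seed; sizes differ by at most one
  set.seed(3)
  labs <- runif(47, 60, 180)
  f1 <- stratifiedFolds(labs, 5L, seed = 9L)
  f2 <- stratifiedFolds(labs, 5L, seed = 9L)
  expect_identical(f1, f2)
  expect_lte(diff(range(table(f1))), 1)
  expect_error(stratifiedFolds(1:3, 5L), "at least z")
  expect_error(stratifiedFolds(1:3, 1L), "at least 2")
})

test_that("stratified folds balance label means better than random folds", {
  set.seed(10)
  labels <- runif(200, 60, 180)
  worst <- function(folds)
    max(abs(tapply(labels, folds, mean) - mean(labels)))
  stratDev <- vapply(1:40, function(s)
    worst(stratifiedFolds(labels, 5L, seed = s)), numeric(1))
  randDev <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    worst(sample(rep_len(1:5, 200)))
  }, numeric(1))
  expect_lt(mean(stratDev), mean(randDev))
})

test_that("the A-Test aggregates fold errors per definition", {
  labels <- runif(60, 60, 180)
  feats <- labels   # features carry the label itself
  oracle <- function(f, l) function(newF) newF
  rep0 <- aTest(feats, labels, oracle, zmax = 5L, seed = 1L)
  expect_equal(unname(rep0@tauByZ), rep(0, 4))
  expect_equal(rep0@tauHat, 0)
  # constant absolute error c shows up as tau = c for every z
  biased <- function(f, l) function(newF) newF + 2.5
  repC <- aTest(feats, labels, biased, zmax = 4L, seed = 2L)
  expect_equal(unname(repC@tauByZ), rep(2.5, 3), tolerance = 1e-12)
  expect_equal(repC@tauHat, 2.5, tolerance = 1e-12)
  expect_equal(repC@tauMin, 2.5, tolerance = 1e-12)
  # zmax = 3 yields two entries averaged per the definition
  rep3 <- aTest(feats, labels, biased, zmax = 3L, seed = 3L)
  expect_length(rep3@tauByZ, 2L)
  expect_equal(rep3@tauHat, mean(rep3@tauByZ))
  expect_lte(rep3@tauMin, rep3@tauHat)
  # training failures are reported with fold context
  broken <- function(f, l) stop("boom")
  expect_error(aTest(feats, labels, broken, zmax = 2L), "z = 2, fold 1")
})

test_that("condition-wise reports group pairs by tag", {
  set.seed(4)
  y <- runif(40, 60, 180)
  p <- y + rnorm(40, sd = 3)
  tags <- rep(c("sitting_relaxed", "speed_8.5"), each = 20)
  reps <- conditionReports(y, p, tags)
  expect_setequal(names(reps), unique(tags))
  expect_equal(reps[["sitting_relaxed"]]@n, 20L)
  expect_equal(reps[["speed_8.5"]]@mae,
               mean(abs((p - y)[21:40])))
})
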