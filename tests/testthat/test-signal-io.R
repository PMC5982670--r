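test_that("recordings round-trip through CSV bit-exactly", {
  set.seed(1)
  ts <- cumsum(runif(200, 0.005, 0.015))
  vals <- matrix(rnorm(200 * 6), ncol = 6)
  rec <- multichannelRecording(ts, vals,
                               channelNames = c("acc_x", "acc_y", "acc_z",
                                                "gyr_x", "gyr_y", "gyr_z"),
                               meta = list(posture = "sitting",
                                           speedKmh = 3.2))
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  back <- readRecording(path, kind = "motion")
  expect_identical(timestamps(back), timestamps(rec))
  expect_identical(signalValues(back), unname(signalValues(rec)))
  expect_identical(channelNames(back), channelNames(rec))
  expect_equal(recordingMeta(back)$posture, "sitting")
  expect_equal(recordingMeta(back)$speedKmh, 3.2)
})

test_that("nominal rate is the median reciprocal inter-sample interval", {
  ts <- seq(0, 9.99, by = 0.01)  # 100 Hz
  rec <- multichannelRecording(ts, matrix(rnorm(1000 * 6), ncol = 6))
  expect_equal(nominalRate(rec), 100, tolerance = 1e-9)
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  expect_equal(nominalRate(readRecording(path, "motion")), 100,
               tolerance = 1e-9)
})

test_that("malformed recordings are rejected", {
  path <- tempfile(fileext = ".csv")
  # two-channel file declared as ECG
  writeLines(c("time,ecg,extra", "0,1,2", "0.1,1,2", "0.2,1,2"), path)
  expect_error(readRecording(path, "ecg"), "wrong channel count")
  # missing time column
  writeLines(c("t,ecg", "0,1", "0.1,1"), path)
  expect_error(readRecording(path, "ecg"), "time column")
  # non-monotone timestamps
  writeLines(c("time,ecg", "0,1", "0.2,1", "0.1,1"), path)
  expect_error(readRecording(path, "ecg"), "non-monotone")
  # empty recording cannot be written
  expect_error(multichannelRecording(numeric(0),
                                     matrix(numeric(0), ncol = 1)),
               "empty recording")
})

test_that("datasets round-trip losslessly including split tags", {
  ds <- randomWindowSet(n = 15L, seed = 4L)
  path <- tempfile(fileext = ".feather")
  saveDataset(ds, path)
  back <- loadDataset(path)
  expect_identical(back@windows, ds@windows)
  expect_identical(hrLabels(back), hrLabels(ds))
  expect_identical(splitTags(back), splitTags(ds))
  expect_identical(back@source$subject, ds@source$subject)
  expect_identical(back@shuffleSeed, ds@shuffleSeed)
  expect_identical(back@splitFractions, ds@splitFractions)
  expect_identical(channelNames(back), channelNames(ds))
})

test_that("tampered dataset containers are rejected on load", {
  ds <- randomWindowSet(n = 5L, nSamp = 32L)
  path <- tempfile(fileext = ".feather")
  saveDataset(ds, path)
  df <- as.data.frame(arrow::read_feather(path))
  df$v1 <- NULL   # drop one value column: shape no longer consistent
  arrow::write_feather(df, path)
  expect_error(loadDataset(path), "shape mismatch")
})

test_that("shuffled 70/10/20 split has exact counts and is reproducible", {
  sets <- replicate(8, randomWindowSet(n = 13L, nSamp = 16L,
                                       withSplit = FALSE),
                    simplify = FALSE)
  ds1 <- buildDataset(sets, shuffleSeed = 42L)
  ds2 <- buildDataset(sets, shuffleSeed = 42L)
  n <- nWindows(ds1)
  expect_equal(n, 8 * 13)
  tb <- table(splitTags(ds1))
  expect_equal(unname(tb[["train"]]), round(0.7 * n))
  expect_equal(unname(tb[["validation"]]), round(0.1 * n))
  expect_equal(unname(tb[["test"]]),
               n - round(0.7 * n) - round(0.1 * n))
  expect_identical(splitTags(ds1), splitTags(ds2))
  ds3 <- buildDataset(sets, shuffleSeed = 43L)
  expect_false(identical(splitTags(ds1), splitTags(ds3)))
})

test_that("subject-grouped split keeps each subject in one split", {
  sets <- lapply(1:10, function(i) {
    s <- randomWindowSet(n = 12L, nSamp = 16L, seed = i,
                         withSplit = FALSE)
    s@source$subject <- sprintf("s%02d", i)
    s
  })
  ds <- buildDataset(sets, shuffleSeed = 1L, bySubject = TRUE)
  bySubj <- split(splitTags(ds), ds@source$subject)
  expect_true(all(vapply(bySubj, function(x) length(unique(x)) == 1L,
                         logical(1))))
  expect_setequal(unique(splitTags(ds)),
                  c("train", "validation", "test"))
})
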