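test_that("depth variants carry the canonical layer counts", {
  want <- c(vgg11 = 8L, vgg13 = 10L, vgg16 = 13L, vgg19 = 16L)
  for (v in names(want)) {
    spec <- modelSpec(v, widthMultiplier = 0.0625)
    net <- buildModel(spec, seed = 1L)
    expect_equal(convLayerCount(net), unname(want[[v]]))
    expect_equal(fcLayerCount(net), 3L)
    expect_equal(featureMapLength(net), 40L)
  }
  # width scaling changes widths, not counts
  wide <- modelSpec("vgg11", widthMultiplier = 0.25)
  narrow <- modelSpec("vgg11", widthMultiplier = 0.0625)
  expect_equal(unlist(wide@stageWidths),
               4L * unlist(narrow@stageWidths))
  expect_equal(convLayerCount(buildModel(wide, 1L)),
               convLayerCount(buildModel(narrow, 1L)))
  expect_gt(parameterCount(buildModel(wide, 1L)),
            parameterCount(buildModel(narrow, 1L)))
})

test_that("the backward pass matches finite-difference gradients", {
  spec <- modelSpec("vgg11", widthMultiplier = 0.03125,
                    inputChannels = 2L, inputLength = 64L, dropoutP = 0)
  net <- buildModel(spec, seed = 42L)
  layers <- net@parameters
  eng <- asNamespace("seismoHR")
  set.seed(7)
  B <- 3L
  X <- matrix(rnorm(2 * 64 * B), nrow = 2)
  y <- rnorm(B, 100, 10)
  lossOf <- function(ly)
    mean((eng$netForward(ly, X, B, 64L, FALSE)$pred - y)^2)
  fwd <- eng$netForward(layers, X, B, 64L, train = TRUE)
  grads <- eng$netBackward(layers, fwd$caches, 2 * (fwd$pred - y) / B, B)
  eps <- 1e-6
  for (li in which(!vapply(grads, is.null, logical(1)))) {
    W <- layers[[li]]$W
    for (k in sample(length(W), min(4L, length(W)))) {
      lp <- layers; lp[[li]]$W[k] <- W[k] + eps
      lm <- layers; lm[[li]]$W[k] <- W[k] - eps
      num <- (lossOf(lp) - lossOf(lm)) / (2 * eps)
      expect_equal(grads[[li]]$W[k], num, tolerance = 1e-3)
    }
    b <- layers[[li]]$b
    k <- sample(length(b), 1L)
    lp <- layers; lp[[li]]$b[k] <- b[k] + eps
    lm <- layers; lm[[li]]$b[k] <- b[k] - eps
    expect_equal(grads[[li]]$b[k], (lossOf(lp) - lossOf(lm)) / (2 * eps),
                 tolerance = 1e-3)
  }
})

test_that("training tracks history and checkpoints the best epoch", {
  ds <- tinyTrainableSet()
  hyper <- trainHyper(learningRate = 3e-3, batchSize = 32L, epochs = 8L,
                      seed = 2L)
  m <- trainModel(tinySpec(), ds, hyper, tag = "tiny")
  expect_equal(nrow(m@history), 8L)
  expect_true(all(is.finite(m@history$valCost)))
  expect_equal(m@bestEpoch, which.min(m@history$valCost))
  # reloading the checkpointed parameters reproduces the best cost
  expect_equal(validationCost(m, ds),
               min(m@history$valCost), tolerance = 1e-5)
  # determinism under identical seeds
  m2 <- trainModel(tinySpec(), ds, hyper, tag = "tiny")
  expect_equal(m@history$valCost, m2@history$valCost, tolerance = 1e-12)
  # empty splits error
  dsNoVal <- ds
  dsNoVal@split[dsNoVal@split == "validation"] <- "train"
  expect_error(trainModel(tinySpec(), dsNoVal, hyper), "validation")
})

test_that("a network learns a constant-label dataset from pure noise", {
  set.seed(4)
  n <- 80L
  ds <- tinyTrainableSet(n = n)
  ds@windows <- array(rnorm(length(ds@windows)), dim = dim(ds@windows))
  ds@labels <- rep(120, n)
  hyper <- trainHyper(learningRate = 3e-3, batchSize = 32L, epochs = 6L,
                      seed = 5L)
  m <- trainModel(tinySpec(), ds, hyper)
  preds <- predictHR(m, ds, split = "test")
  expect_lt(mean(abs(preds - 120)), 2)
})

test_that("prediction is deterministic, finite and shape-checked", {
  ds <- tinyTrainableSet()
  m <- trainModel(tinySpec(), ds,
                  trainHyper(learningRate = 3e-3, batchSize = 32L,
                             epochs = 3L, seed = 7L))
  arr <- windowArray(ds, "test")
  p1 <- predictHR(m, arr, split = NULL)
  expect_length(p1, dim(arr)[1])
  expect_true(all(is.finite(p1)))
  # duplicated window gives identical estimates (dropout off at inference)
  dup <- arr[c(1, 1), , , drop = FALSE]
  pd <- predictHR(m, dup, split = NULL)
  expect_equal(pd[1], pd[2])
  # an all-zero window still yields a finite estimate
  zero <- array(0, dim = c(1, dim(arr)[2], dim(arr)[3]))
  expect_true(is.finite(predictHR(m, zero, split = NULL)))
  # shape mismatch errors
  bad <- array(0, dim = c(2, 3, dim(arr)[3]))
  expect_error(predictHR(m, bad, split = NULL), "shape")
})

test_that("ensemble prediction is the member mean", {
  ds <- tinyTrainableSet()
  hyperA <- trainHyper(learningRate = 3e-3, batchSize = 32L, epochs = 3L,
                       seed = 1L)
  hyperB <- trainHyper(learningRate = 3e-3, batchSize = 32L, epochs = 3L,
                       seed = 2L)
  a <- trainModel(tinySpec(), ds, hyperA, tag = "a")
  b <- trainModel(tinySpec(), ds, hyperB, tag = "b")
  ens <- ensembleModel(a, b)
  pa <- predictHR(a, ds)
  pb <- predictHR(b, ds)
  expect_equal(predictHR(ens, ds), (pa + pb) / 2, tolerance = 1e-12)
  # identical members collapse to the member prediction
  expect_equal(predictHR(ensembleModel(a, a), ds), pa, tolerance = 1e-12)
  # permutation invariance in the members
  expect_equal(predictHR(ensembleModel(b, a), ds),
               predictHR(ens, ds), tolerance = 1e-12)
})
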