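# Shared fixtures, built in code. Expensive objects are cached for the
# duration of the test run.

fixtureEnv <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixtureEnv)) {
    assign(key, builder(), envir = fixtureEnv)
  }
  get(key, envir = fixtureEnv)
}

# A short constant-rate session: 60 s sitting/relaxed at the given bpm.
quietSession <- function(hr = 72, durationS = 60, seed = 5L,
                         rrJitterCv = 0) {
  simulateSession(conditionSpec(posture = "sitting",
                                physicalState = "relaxed",
                                durationS = durationS, hrBpm = hr,
                                seed = seed, rrJitterCv = rrJitterCv))
}

# Small labeled window set with random contents (not simulator output),
# for io/augmentation mechanics.
randomWindowSet <- function(n = 20L, nCh = 6L, nSamp = 1280L, seed = 1L,
                            withSplit = TRUE) {
  set.seed(seed)
  windows <- array(rnorm(n * nCh * nSamp), dim = c(n, nCh, nSamp))
  labels <- runif(n, 60, 200)
  split <- if (withSplit)
    sample(c("train", "validation", "test"), n, replace = TRUE,
           prob = c(0.7, 0.1, 0.2))
  else rep(NA_character_, n)
  new("LabeledWindowSet", windows = windows, labels = labels,
      split = split,
      source = data.frame(subject = rep("sX", n), condition = rep("t", n),
                          windowStart = seq_len(n) - 1),
      splitFractions = c(0.7, 0.1, 0.2), shuffleSeed = 1L,
      channelNames = paste0("ch", seq_len(nCh)), sampleRate = 256,
      meta = list())
}

# A tiny architecture + hyperparameters that train in well under a second.
tinySpec <- function(variant = "vgg11", dropoutP = 0.5) {
  modelSpec(variant, widthMultiplier = 0.0625, inputChannels = 6L,
            inputLength = 64L, dropoutP = dropoutP)
}

# Window set shaped for tinySpec: labels linearly decodable from a simple
# feature so little training suffices.
tinyTrainableSet <- function(n = 120L, seed = 3L) {
  set.seed(seed)
  nCh <- 6L; nSamp <- 64L
  labels <- runif(n, 60, 180)
  windows <- array(rnorm(n * nCh * nSamp, sd = 0.1),
                   dim = c(n, nCh, nSamp))
  for (i in seq_len(n))   # amplitude encodes the label
    windows[i, , ] <- windows[i, , ] + labels[i] / 100
  split <- rep("train", n)
  split[seq_len(round(0.15 * n))] <- "validation"
  split[round(0.15 * n) + seq_len(round(0.15 * n))] <- "test"
  new("LabeledWindowSet", windows = windows, labels = labels,
      split = split,
      source = data.frame(subject = "sX", condition = "t",
                          windowStart = seq_len(n) - 1),
      splitFractions = c(0.7, 0.1, 0.2), shuffleSeed = 1L,
      channelNames = paste0("ch", seq_len(nCh)), sampleRate = 256,
      meta = list())
}
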