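# The scaled-down learnability corpus: ~2,000 windows from constant-rate
# 60 s sessions with heart rate uniform in 60-180 bpm under generator
# defaults. Shared (cached) between the recovery and structural-risk
# experiments.

recoveryDataset <- function() {
  cached("recoveryDs", function() {
    nSess <- 36L
    set.seed(99)
    hrs <- runif(nSess, 60, 180)
    sessions <- lapply(seq_len(nSess), function(i)
      simulateSession(conditionSpec(posture = "sitting",
                                    physicalState = "relaxed",
                                    durationS = 60, hrBpm = hrs[i],
                                    subject = sprintf("s%02d", i),
                                    seed = 500L + i)))
    buildDataset(sessions, shuffleSeed = 7L)
  })
}

# Constant-output network: a real layer stack with zeroed weights and the
# output bias pinned, so ensemble arithmetic can be checked end to end.
constantModel <- function(value, spec = tinySpec(), tag = "const") {
  net <- buildModel(spec, seed = 1L)
  layers <- lapply(net@parameters, function(ly) {
    if (!is.null(ly$W)) ly$W[] <- 0
    ly
  })
  layers[[length(layers)]]$b <- value
  hist <- data.frame(epoch = 1L, trainCost = 0, valCost = 0)
  new("TrainedModel", spec = spec, hyper = trainHyper(), parameters = layers,
      history = hist, bestEpoch = 1L, tag = tag)
}
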