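#' @include AllClasses.R
NULL

checkPairs <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (any(yTrue <= 0)) stop("all true labels must be positive")
}

#' Mean relative accuracy (percent)
#'
#' `100 * (1 - mean(|yPred - yTrue| / yTrue))`: the complement of the mean
#' absolute relative error, in percent. Invariant under joint positive
#' rescaling of labels and estimates.
#'
#' @param yTrue true heart rates (bpm), all positive.
#' @param yPred estimated heart rates (bpm).
#' @return accuracy in percent.
#' @export
hrAccuracy <- function(yTrue, yPred) {
  checkPairs(yTrue, yPred)
  100 * (1 - mean(abs(yPred - yTrue) / yTrue))
}

#' Agreement metrics between estimated and true heart rate
#'
#' MAE is the mean absolute error, SDAE the population (1/n) standard
#' deviation of the absolute errors, RMSE the root mean squared error, and
#' CC the Pearson correlation of labels and estimates (NA with a warning
#' when either side has zero variance). The relative accuracy of
#' [hrAccuracy()] is included.
#'
#' @inheritParams hrAccuracy
#' @return an [EvalReport-class].
#' @export
errorMetrics <- function(yTrue, yPred) {
  checkPairs(yTrue, yPred)
  n <- length(yTrue)
  if (n < 2L) stop("need at least 2 pairs")
  d <- yPred - yTrue
  a <- abs(d)
  cc <- if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0) {
    warning("correlation undefined: zero variance")
    NA_real_
  } else {
    stats::cor(yTrue, yPred)
  }
  new("EvalReport", accuracyPct = hrAccuracy(yTrue, yPred),
      mae = mean(a), sdae = sqrt(mean((a - mean(a))^2)),
      rmse = sqrt(mean(d^2)), cc = cc, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair mean `(yTrue + yPred)/2` against difference `yPred - yTrue`,
#' with 95% limits of agreement at the mean difference plus/minus 1.96
#' population standard deviations of the differences.
#'
#' @inheritParams hrAccuracy
#' @return a [BlandAltmanResult-class].
#' @export
blandAltman <- function(yTrue, yPred) {
  checkPairs(yTrue, yPred)
  if (length(yTrue) < 2L) stop("need at least 2 pairs")
  d <- yPred - yTrue
  m <- (yPred + yTrue) / 2
  meanDiff <- mean(d)
  sdDiff <- sqrt(mean((d - meanDiff)^2))
  new("BlandAltmanResult", meanDiff = meanDiff, sdDiff = sdDiff,
      loaLow = meanDiff - 1.96 * sdDiff,
      loaHigh = meanDiff + 1.96 * sdDiff,
      pairs = data.frame(mean = m, difference = d))
}

#' Per-condition agreement reports
#'
#' Groups paired estimates by a condition tag and computes one
#' [EvalReport-class] per group.
#'
#' @inheritParams hrAccuracy
#' @param tags character vector of per-pair condition labels.
#' @return named list of [EvalReport-class] objects.
#' @export
conditionReports <- function(yTrue, yPred, tags) {
  stopifnot(length(tags) == length(yTrue))
  out <- lapply(split(seq_along(tags), tags), function(idx)
    errorMetrics(yTrue[idx], yPred[idx]))
  out
}

#' Heart-rate-stratified fold assignment
#'
#' Sorts the labels and deals consecutive sorted runs of length z to the z
#' folds round-robin, shuffling within each run (seeded), so every fold's
#' label distribution matches the pooled distribution and fold sizes differ
#' by at most one.
#'
#' @param labels heart-rate labels in bpm.
#' @param z fold count, `2 <= z <= length(labels)`.
#' @param seed integer seed for the within-run shuffles.
#' @return integer vector of fold ids (1..z), aligned with `labels`.
#' @export
stratifiedFolds <- function(labels, z, seed = 1L) {
  n <- length(labels)
  if (z < 2L) stop("z must be at least 2")
  if (n < z) stop("need at least z labels")
  ord <- order(labels)
  folds <- integer(n)
  withSeed(seed, {
    at <- 1L
    while (at <= n) {
      run <- ord[at:min(n, at + z - 1L)]
      folds[run] <- sample.int(z, length(run))
      at <- at + z
    }
  })
  folds
}

#' A-Test structural-risk assessment
#'
#' For each fold count z from 2 to `zmax`, builds heart-rate-stratified z
#' folds, fits the supplied training procedure on all but one fold and
#' measures the mean absolute error on the held-out fold; the regression
#' error tau(z) is the mean of the z fold MAEs. The structural-risk summary
#' aggregates tau-hat = sum over z of tau(z) / (zmax - 1) together with the
#' minimum tau; a low tau-hat corresponds to low structural risk.
#'
#' @param features training inputs: a 3-d window array, matrix (rows =
#'   cases) or vector, indexed in parallel with `labels`.
#' @param labels heart-rate labels in bpm.
#' @param trainer a function `(featuresTrain, labelsTrain)` returning a
#'   prediction function `(featuresTest) -> estimates`; must be
#'   deterministic given its inputs for a reproducible report.
#' @param zmax largest fold count (default 10).
#' @param seed integer seed for the fold assignments.
#' @return an [ATestReport-class].
#' @export
aTest <- function(features, labels, trainer, zmax = 10L, seed = 1L) {
  if (zmax < 2L) stop("zmax must be at least 2")
  zs <- seq(2L, zmax)
  tau <- stats::setNames(numeric(length(zs)), paste0("z", zs))
  for (j in seq_along(zs)) {
    z <- zs[j]
    folds <- stratifiedFolds(labels, z, seed = deriveSeed(seed, z))
    maes <- numeric(z)
    for (f in seq_len(z)) {
      trIdx <- which(folds != f)
      teIdx <- which(folds == f)
      predict <- tryCatch(
        trainer(subsetFeatures(features, trIdx), labels[trIdx]),
        error = function(e)
          stop(sprintf("training failed at z = %d, fold %d: %s",
                       z, f, conditionMessage(e))))
      preds <- predict(subsetFeatures(features, teIdx))
      maes[f] <- mean(abs(preds - labels[teIdx]))
    }
    tau[j] <- mean(maes)
  }
  new("ATestReport", tauByZ = tau, tauHat = sum(tau) / (zmax - 1L),
      tauMin = min(tau), zmax = as.integer(zmax))
}

subsetFeatures <- function(features, idx) {
  if (is.array(features) && length(dim(features)) == 3L)
    features[idx, , , drop = FALSE]
  else if (is.matrix(features))
    features[idx, , drop = FALSE]
  else features[idx]
}

#' Network training procedure for the A-Test
#'
#' Wraps the package's training harness into the `(features, labels) ->
#' predictor` closure [aTest()] consumes: a fraction of each training set
#' is carved out (seeded) as the validation split for best-epoch
#' checkpointing.
#'
#' @param spec a [ModelSpec-class].
#' @param hyper a [TrainHyper-class].
#' @param valFraction fraction of the training cases used for validation
#'   (default 0.1).
#' @return a trainer function for [aTest()].
#' @export
cnnTrainer <- function(spec, hyper = trainHyper(), valFraction = 0.1) {
  force(spec); force(hyper); force(valFraction)
  function(features, labels) {
    n <- length(labels)
    nVal <- max(1L, round(valFraction * n))
    ord <- withSeed(deriveSeed(hyper@seed, 211L), sample.int(n))
    vaIdx <- ord[seq_len(nVal)]
    trIdx <- ord[(nVal + 1L):n]
    model <- buildModel(spec, seed = hyper@seed)
    fit <- fitLayers(model@parameters,
                     flattenWindows(subsetFeatures(features, trIdx)),
                     labels[trIdx],
                     flattenWindows(subsetFeatures(features, vaIdx)),
                     labels[vaIdx], spec, hyper)
    function(newFeatures) {
      d <- dim(newFeatures)
      netPredict(fit$layers, flattenWindows(newFeatures), d[1],
                 spec@inputLength)
    }
  }
}
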