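#' @include AllGenerics.R
NULL

#' @describeIn channelNames channel labels of a recording.
#' @export
setMethod("channelNames", "MultichannelRecording",
          function(x) x@channelNames)

#' @describeIn channelNames channel labels of a window set.
#' @export
setMethod("channelNames", "LabeledWindowSet", function(x) x@channelNames)

#' @describeIn timestamps sample times of a recording.
#' @export
setMethod("timestamps", "MultichannelRecording", function(x) x@timestamps)

#' @describeIn signalValues values matrix of a recording.
#' @export
setMethod("signalValues", "MultichannelRecording", function(x) x@values)

#' @describeIn nominalRate nominal rate of a recording.
#' @export
setMethod("nominalRate", "MultichannelRecording", function(x) x@nominalRate)

#' @describeIn recordingMeta metadata of a recording.
#' @export
setMethod("recordingMeta", "MultichannelRecording", function(x) x@meta)

#' @describeIn recordingMeta metadata of a window set.
#' @export
setMethod("recordingMeta", "LabeledWindowSet", function(x) x@meta)

#' @describeIn nWindows window count.
#' @export
setMethod("nWindows", "LabeledWindowSet", function(x)
  dim(x@windows)[1])

#' @describeIn hrLabels labels of a window set.
#' @export
setMethod("hrLabels", "LabeledWindowSet", function(x) x@labels)

#' @describeIn splitTags split tags of a window set.
#' @export
setMethod("splitTags", "LabeledWindowSet", function(x) x@split)

#' @describeIn windowArray window tensor, optionally restricted to a split.
#' @export
setMethod("windowArray", "LabeledWindowSet", function(x, split = NULL) {
  if (is.null(split)) return(x@windows)
  keep <- which(!is.na(x@split) & x@split == split)
  x@windows[keep, , , drop = FALSE]
})

#' @describeIn getWindow extract one window with its label and provenance.
#' @export
setMethod("getWindow", "LabeledWindowSet", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nWindows(x))
  list(data = x@windows[i, , ], label = x@labels[i],
       source = x@source[i, , drop = FALSE])
})

setMethod("show", "MultichannelRecording", function(object) {
  n <- length(object@timestamps)
  span <- if (n) diff(range(object@timestamps)) else 0
  cat(sprintf(
    "MultichannelRecording: %d channel(s) x %d samples, %.1f s @ ~%.1f Hz\n",
    ncol(object@values), n, span, object@nominalRate))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "ConditionSpec", function(object) {
  cat(sprintf(
    "ConditionSpec: %s/%s, speed %g km/h, %.0f s, HR %g-%g bpm, SNR %g dB\n",
    object@posture, object@physicalState, object@speedKmh, object@durationS,
    min(object@hrBpm), max(object@hrBpm), object@snrDb))
})

setMethod("show", "SimulatedSession", function(object) {
  cat(sprintf("SimulatedSession: %d beats over %.0f s (%s/%s, %g km/h)\n",
              length(object@trueBeatTimes), object@spec@durationS,
              object@spec@posture, object@spec@physicalState,
              object@spec@speedKmh))
})

setMethod("show", "RPeakSeries", function(object) {
  n <- length(object@peakTimes)
  if (n >= 2) {
    rr <- diff(object@peakTimes)
    cat(sprintf("RPeakSeries: %d peaks, mean RR %.3f s (%.1f bpm)\n",
                n, mean(rr), 60 / mean(rr)))
  } else {
    cat(sprintf("RPeakSeries: %d peak(s)\n", n))
  }
})

setMethod("show", "LabeledWindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("LabeledWindowSet: %d windows (%d ch x %d samples @ %g Hz)\n",
              d[1], d[2], d[3], object@sampleRate))
  if (d[1]) {
    cat(sprintf("  labels: %.1f-%.1f bpm\n",
                min(object@labels), max(object@labels)))
    tb <- table(factor(object@split,
                       levels = c("train", "validation", "test")))
    if (sum(tb) > 0)
      cat(sprintf("  split: %d train / %d validation / %d test\n",
                  tb[["train"]], tb[["validation"]], tb[["test"]]))
  }
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf(
    "ModelSpec: %s (1-D), %d conv + 3 FC layers, width x%g, input %d x %d\n",
    object@variant, sum(lengths(object@stageWidths)),
    object@widthMultiplier, object@inputChannels, object@inputLength))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf(
    "TrainedModel [%s]: %s, best epoch %d/%d (val cost %.4g)\n",
    object@tag, object@spec@variant, object@bestEpoch,
    nrow(object@history), object@history$valCost[object@bestEpoch]))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel [%s]: mean of [%s] and [%s]\n", object@tag,
              object@memberA@tag, object@memberB@tag))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    paste0("EvalReport (n = %d): accuracy %.2f%%, MAE %.2f, SDAE %.2f, ",
           "RMSE %.2f bpm, CC %.3f\n"),
    object@n, object@accuracyPct, object@mae, object@sdae, object@rmse,
    object@cc))
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf(
    "BlandAltman: mean diff %.2f bpm, 95%% LOA [%.2f, %.2f] bpm\n",
    object@meanDiff, object@loaLow, object@loaHigh))
})

setMethod("show", "ATestReport", function(object) {
  cat(sprintf("ATestReport (zmax = %d): tau-hat %.3f, min tau %.3f bpm\n",
              object@zmax, object@tauHat, object@tauMin))
  z <- seq(2L, object@zmax)
  cat("  tau by z:",
      paste(sprintf("z=%d: %.3f", z, object@tauByZ), collapse = ", "), "\n")
})
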