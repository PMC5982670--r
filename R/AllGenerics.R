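#' @include AllClasses.R
NULL

#' Channel labels of a recording or window set
#' @param x a [MultichannelRecording-class] or [LabeledWindowSet-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Sample timestamps (seconds)
#' @param x a [MultichannelRecording-class].
#' @return numeric vector of sample times.
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' Signal values matrix (samples x channels)
#' @param x a [MultichannelRecording-class].
#' @return numeric matrix.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' Nominal sampling rate (Hz)
#' @param x a [MultichannelRecording-class].
#' @return a single number.
#' @export
setGeneric("nominalRate", function(x) standardGeneric("nominalRate"))

#' Free-form metadata tags
#' @param x a recording or window set.
#' @return a list.
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' Number of windows in a window set
#' @param x a [LabeledWindowSet-class].
#' @return integer count.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' Heart-rate labels (bpm)
#' @param x a [LabeledWindowSet-class].
#' @return numeric vector of labels.
#' @export
setGeneric("hrLabels", function(x) standardGeneric("hrLabels"))

#' Train/validation/test split tags
#' @param x a [LabeledWindowSet-class].
#' @return character vector of split tags (possibly NA).
#' @export
setGeneric("splitTags", function(x) standardGeneric("splitTags"))

#' Window tensor (window x channel x sample)
#' @param x a [LabeledWindowSet-class].
#' @param split optional split tag to subset to ("train", "validation",
#'   "test").
#' @return 3-d numeric array.
#' @export
setGeneric("windowArray", function(x, split = NULL)
  standardGeneric("windowArray"))

#' One labeled window
#' @param x a [LabeledWindowSet-class].
#' @param i window index.
#' @return list with elements `data` (channels x samples matrix), `label`
#'   (bpm) and `source` (one-row provenance data.frame).
#' @export
setGeneric("getWindow", function(x, i) standardGeneric("getWindow"))

#' Predict heart rate for motion windows
#'
#' @param object a [TrainedModel-class] or [EnsembleModel-class]; ensemble
#'   prediction is the arithmetic mean of the member predictions.
#' @param windows a [LabeledWindowSet-class] or a 3-d array (window x
#'   channel x sample) conforming to the model's input geometry.
#' @param split when `windows` is a window set, the split tag to predict for
#'   (default "test"); use NULL for all windows.
#' @return numeric vector of heart-rate estimates in bpm, one per window.
#' @export
setGeneric("predictHR", function(object, windows, split = "test")
  standardGeneric("predictHR"))
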