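#' @import methods
NULL

# Channel layout shared by the whole package: six motion axes, in this order.
MOTION_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

#' Multichannel biosignal recording
#'
#' Container for a timestamped multi-channel signal: either a six-axis
#' chest-motion recording (tri-axis accelerometer + tri-axis gyroscope) or a
#' single-lead ECG. Timestamps are seconds, strictly increasing and possibly
#' irregular; `values` holds one row per timestamp and one column per channel.
#'
#' @slot channelNames character vector of channel labels (column order of
#'   `values`); 6 channels for motion, 1 for ECG.
#' @slot timestamps numeric vector of sample times in seconds.
#' @slot values numeric matrix, `length(timestamps)` rows.
#' @slot nominalRate nominal sampling rate in Hz; estimated as the median
#'   reciprocal inter-sample interval when not supplied.
#' @slot meta free-form list of condition tags (posture, physical state,
#'   speed, subject id, ...).
#'
#' @exportClass MultichannelRecording
setClass("MultichannelRecording",
  slots = c(
    channelNames = "character",
    timestamps   = "numeric",
    values       = "matrix",
    nominalRate  = "numeric",
    meta         = "list"
  )
)

setValidity("MultichannelRecording", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@timestamps))
    msg <- c(msg, "values row count must equal timestamp count")
  if (ncol(object@values) != length(object@channelNames))
    msg <- c(msg, "values column count must equal number of channel names")
  if (length(object@timestamps) > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@nominalRate) != 1 || !is.finite(object@nominalRate) ||
      object@nominalRate <= 0)
    msg <- c(msg, "nominalRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MultichannelRecording
#'
#' @param timestamps sample times in seconds, strictly increasing.
#' @param values numeric matrix (samples x channels) or a vector for a
#'   single-channel recording.
#' @param channelNames channel labels; defaults to `colnames(values)`.
#' @param nominalRate sampling rate in Hz; when `NULL`, estimated as the
#'   median of the reciprocal inter-sample intervals.
#' @param meta free-form list of condition tags.
#' @return a validated [MultichannelRecording-class] object.
#' @export
multichannelRecording <- function(timestamps, values, channelNames = NULL,
                                  nominalRate = NULL, meta = list()) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channelNames)) channelNames <- colnames(values)
  dimnames(values) <- NULL
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(ncol(values)))
  if (length(timestamps) == 0L) stop("empty recording")
  if (is.null(nominalRate)) {
    if (length(timestamps) < 2L)
      stop("cannot estimate nominal rate from fewer than 2 samples")
    nominalRate <- stats::median(1 / diff(timestamps))
  }
  new("MultichannelRecording",
      channelNames = as.character(channelNames),
      timestamps = as.numeric(timestamps), values = values,
      nominalRate = as.numeric(nominalRate), meta = meta)
}

#' Simulated measurement-condition specification
#'
#' Describes one recording session of the measurement protocol being emulated: two
#' physical states (relaxed/aroused), three postures (sitting, standing,
#' supine) and six treadmill speeds (3.2-10.3 km/h). Speed 0 denotes a
#' posture condition; speed conditions are performed standing.
#'
#' @slot posture "sitting", "standing" or "supine".
#' @slot physicalState "relaxed" or "aroused".
#' @slot speedKmh 0 or one of 3.2, 4.5, 5.8, 6.4, 8.5, 10.3.
#' @slot durationS session duration in seconds.
#' @slot hrTime,hrBpm knots of the target heart-rate trajectory (bpm,
#'   linearly interpolated; a single knot means constant heart rate).
#' @slot snrDb cardiac-pulse-to-interference power ratio in dB.
#' @slot rrJitterCv coefficient of variation of the beat-to-beat (RR)
#'   interval jitter; 0 gives metronomic beats.
#' @slot subject subject identifier carried into provenance.
#' @slot seed integer seed governing all randomness of the session.
#' @exportClass ConditionSpec
setClass("ConditionSpec",
  slots = c(
    posture       = "character",
    physicalState = "character",
    speedKmh      = "numeric",
    durationS     = "numeric",
    hrTime        = "numeric",
    hrBpm         = "numeric",
    snrDb         = "numeric",
    rrJitterCv    = "numeric",
    subject       = "character",
    seed          = "integer"
  )
)

SPEEDS_KMH <- c(3.2, 4.5, 5.8, 6.4, 8.5, 10.3)

setValidity("ConditionSpec", function(object) {
  msg <- character()
  if (!object@posture %in% c("sitting", "standing", "supine"))
    msg <- c(msg, "posture must be sitting, standing or supine")
  if (!object@physicalState %in% c("relaxed", "aroused"))
    msg <- c(msg, "physicalState must be relaxed or aroused")
  if (object@speedKmh != 0 && !object@speedKmh %in% SPEEDS_KMH)
    msg <- c(msg, sprintf("unknown speed value: %g km/h", object@speedKmh))
  if (object@speedKmh != 0 && object@posture != "standing")
    msg <- c(msg, "speed conditions use posture = standing")
  if (object@durationS <= 0) msg <- c(msg, "duration must be positive")
  if (length(object@hrTime) != length(object@hrBpm) ||
      length(object@hrBpm) < 1L)
    msg <- c(msg, "hrTime and hrBpm must be equal-length, non-empty")
  if (any(object@hrBpm < 40 | object@hrBpm > 220))
    msg <- c(msg, "heart-rate profile must stay within [40, 220] bpm")
  if (object@rrJitterCv < 0) msg <- c(msg, "rrJitterCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Paired synthetic session: six-axis motion + ECG with known beats
#'
#' @slot motion six-channel [MultichannelRecording-class] at an irregular
#'   rate in \[100, 200\] Hz.
#' @slot ecg single-channel [MultichannelRecording-class] at 512 Hz.
#' @slot trueBeatTimes ground-truth beat (R-peak) times in seconds.
#' @slot spec the [ConditionSpec-class] that generated the session.
#' @exportClass SimulatedSession
setClass("SimulatedSession",
  slots = c(
    motion        = "MultichannelRecording",
    ecg           = "MultichannelRecording",
    trueBeatTimes = "numeric",
    spec          = "ConditionSpec"
  )
)

#' Detected R-peak series
#'
#' @slot peakTimes R-peak times in seconds, strictly increasing, with a
#'   physiological refractory gap of at least 0.2 s.
#' @slot detectionMeta list of detector settings and final thresholds.
#' @exportClass RPeakSeries
setClass("RPeakSeries",
  slots = c(peakTimes = "numeric", detectionMeta = "list")
)

setValidity("RPeakSeries", function(object) {
  pt <- object@peakTimes
  if (length(pt) > 1 && any(diff(pt) < 0.2 - 1e-9))
    return("peak times must be >= 0.2 s apart (refractory constraint)")
  if (length(pt) > 1 && any(diff(pt) <= 0))
    return("peak times must be strictly increasing")
  TRUE
})

#' Labeled window set
#'
#' The dataset the network consumes: fixed-size six-channel motion windows
#' (5 s at 256 Hz = 1280 samples/channel after preprocessing), each with a
#' heart-rate label in bpm and provenance, optionally tagged with a
#' train/validation/test split.
#'
#' @slot windows numeric array `n x channels x samples`.
#' @slot labels heart rate per window (bpm), within the keep-range enforced
#'   upstream (60-200 bpm).
#' @slot split per-window split tag: "train", "validation", "test", or NA
#'   before splitting.
#' @slot source data.frame with one row per window (subject, condition,
#'   windowStart).
#' @slot splitFractions train/validation/test fractions (0.70, 0.10, 0.20).
#' @slot shuffleSeed seed used for the shuffle-then-slice split (NA before
#'   splitting).
#' @slot channelNames channel labels.
#' @slot sampleRate window sampling rate in Hz (256).
#' @slot meta free-form list (candidate/excluded window counts, config).
#' @exportClass LabeledWindowSet
setClass("LabeledWindowSet",
  slots = c(
    windows        = "array",
    labels         = "numeric",
    split          = "character",
    source         = "data.frame",
    splitFractions = "numeric",
    shuffleSeed    = "integer",
    channelNames   = "character",
    sampleRate     = "numeric",
    meta           = "list"
  )
)

setValidity("LabeledWindowSet", function(object) {
  msg <- character()
  d <- dim(object@windows)
  if (length(d) != 3L)
    msg <- c(msg, "windows must be a 3-d array (window x channel x sample)")
  else {
    if (d[1] != length(object@labels))
      msg <- c(msg, "one label per window required")
    if (d[1] != length(object@split))
      msg <- c(msg, "one split tag per window required")
    if (d[2] != length(object@channelNames))
      msg <- c(msg, "channel count must match channelNames")
    if (d[1] != nrow(object@source))
      msg <- c(msg, "one source row per window required")
  }
  if (!all(is.na(object@split) |
           object@split %in% c("train", "validation", "test")))
    msg <- c(msg, "split tags must be train/validation/test or NA")
  if (length(object@splitFractions) != 3L ||
      abs(sum(object@splitFractions) - 1) > 1e-9)
    msg <- c(msg, "splitFractions must be three values summing to 1")
  if (length(msg)) msg else TRUE
})

#' Augmentation policy
#'
#' Per-operator parameters and copy counts governing training-set expansion.
#' Each augmented copy composes scaling, jittering and circular permutation
#' with per-copy random draws.
#'
#' @slot permAlpha integer sample shift for the permutation operator, or NA
#'   to draw uniformly over \[0, n) per copy.
#' @slot jitterRange range the Gaussian-noise SD is drawn from
#'   (post-normalization units); a single value fixes the SD.
#' @slot scaleRange range the scaling ratio is drawn from; must stay > -1.
#' @slot copiesPerSample augmented copies emitted per training window.
#' @slot seed integer seed for all per-copy draws.
#' @exportClass AugmentationPolicy
setClass("AugmentationPolicy",
  slots = c(
    permAlpha       = "integer",
    jitterRange     = "numeric",
    scaleRange      = "numeric",
    copiesPerSample = "integer",
    seed            = "integer"
  )
)

setValidity("AugmentationPolicy", function(object) {
  msg <- character()
  if (any(object@jitterRange < 0))
    msg <- c(msg, "jitter SD must be >= 0")
  if (any(object@scaleRange <= -1))
    msg <- c(msg, "scaling ratio must stay > -1")
  if (object@copiesPerSample < 0L)
    msg <- c(msg, "copiesPerSample must be >= 0")
  if (!is.na(object@permAlpha) && object@permAlpha < 0L)
    msg <- c(msg, "permutation shift must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Preprocessing configuration
#'
#' @slot targetRate resampling rate in Hz (256).
#' @slot sgOrder Savitzky-Golay polynomial order (2).
#' @slot sgWindow Savitzky-Golay window in samples (31, odd; about 121 ms at
#'   256 Hz).
#' @slot windowS sliding-window length in seconds (5).
#' @slot strideS sliding-window stride in seconds (1).
#' @slot hrMin,hrMax label keep-range in bpm (60, 200); windows outside are
#'   excluded as presumed ECG artifacts.
#' @slot normalizeScope "window" (per channel per window, default) or
#'   "recording" (per channel over the whole recording).
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  slots = c(
    targetRate     = "numeric",
    sgOrder        = "integer",
    sgWindow       = "integer",
    windowS        = "numeric",
    strideS        = "numeric",
    hrMin          = "numeric",
    hrMax          = "numeric",
    normalizeScope = "character"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@sgWindow %% 2L == 0L || object@sgWindow <= object@sgOrder)
    msg <- c(msg, "sgWindow must be odd and greater than sgOrder")
  n <- object@windowS * object@targetRate
  if (abs(n - round(n)) > 1e-9)
    msg <- c(msg, "windowS x targetRate must be an integer sample count")
  if (object@strideS <= 0) msg <- c(msg, "strideS must be positive")
  if (object@hrMin >= object@hrMax)
    msg <- c(msg, "hrMin must be below hrMax")
  if (!object@normalizeScope %in% c("window", "recording"))
    msg <- c(msg, "normalizeScope must be 'window' or 'recording'")
  if (length(msg)) msg else TRUE
})

#' Network architecture specification (1-D VGG variants)
#'
#' @slot variant "vgg11", "vgg13", "vgg16" or "vgg19".
#' @slot stageWidths list of per-stage conv channel counts (after width
#'   scaling).
#' @slot fcWidths the two hidden fully-connected layer sizes.
#' @slot dropoutP dropout probability on the hidden FC layers (0.5).
#' @slot widthMultiplier scaling applied to the canonical widths.
#' @slot inputChannels,inputLength input geometry (6 channels x 1280).
#' @exportClass ModelSpec
setClass("ModelSpec",
  slots = c(
    variant         = "character",
    stageWidths     = "list",
    fcWidths        = "integer",
    dropoutP        = "numeric",
    widthMultiplier = "numeric",
    inputChannels   = "integer",
    inputLength     = "integer"
  )
)

VGG_CONV_COUNTS <- c(vgg11 = 8L, vgg13 = 10L, vgg16 = 13L, vgg19 = 16L)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@variant %in% names(VGG_CONV_COUNTS))
    msg <- c(msg, sprintf("unknown variant '%s'", object@variant))
  else if (sum(lengths(object@stageWidths)) !=
           VGG_CONV_COUNTS[[object@variant]])
    msg <- c(msg, "conv-layer count does not match variant")
  if (length(object@stageWidths) != 5L)
    msg <- c(msg, "expected 5 conv stages (5 pooling steps)")
  if (length(object@fcWidths) != 2L)
    msg <- c(msg, "expected two hidden fully-connected widths")
  if (object@inputLength %% 2L^5L != 0L)
    msg <- c(msg, "inputLength must be divisible by 2^5 for the 5 poolings")
  if (length(msg)) msg else TRUE
})

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe: L2 loss, Adam at learning rate
#' 1e-4, 128-sized minibatches, 100 epochs, Xavier initialization, rectified
#' linear activations.
#'
#' @slot learningRate Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot epochs training epochs; the checkpoint kept is the one with the
#'   lowest validation cost.
#' @slot centerOutputBias if TRUE, the output bias starts at the mean
#'   training label (weights remain Xavier).
#' @slot seed integer seed for init, shuffling and dropout.
#' @exportClass TrainHyper
setClass("TrainHyper",
  slots = c(
    learningRate     = "numeric",
    batchSize        = "integer",
    epochs           = "integer",
    centerOutputBias = "logical",
    seed             = "integer"
  )
)

setValidity("TrainHyper", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Untrained network
#'
#' @slot spec the [ModelSpec-class].
#' @slot parameters list of layer descriptors with initialized weights.
#' @slot initSeed seed used for Xavier initialization.
#' @exportClass HRNet
setClass("HRNet",
  slots = c(spec = "ModelSpec", parameters = "list", initSeed = "integer")
)

#' Trained network with checkpoint-selection metadata
#'
#' @slot spec the [ModelSpec-class].
#' @slot hyper the [TrainHyper-class] used.
#' @slot parameters fitted weights from the best-validation epoch.
#' @slot history data.frame with per-epoch train/validation cost.
#' @slot bestEpoch epoch whose parameters are stored (argmin validation
#'   cost).
#' @slot tag free label, e.g. "vgg16_noaug".
#' @exportClass TrainedModel
setClass("TrainedModel",
  slots = c(
    spec       = "ModelSpec",
    hyper      = "TrainHyper",
    parameters = "list",
    history    = "data.frame",
    bestEpoch  = "integer",
    tag        = "character"
  )
)

setValidity("TrainedModel", function(object) {
  if (nrow(object@history) > 0 &&
      object@bestEpoch != which.min(object@history$valCost))
    return("bestEpoch must be the argmin of the validation cost")
  TRUE
})

#' Two-member ensemble
#'
#' Prediction is the arithmetic mean of the member predictions. The
#' optimal configuration pairs a VGG-16 trained without augmentation with a
#' VGG-19 trained with augmentation.
#'
#' @slot memberA,memberB the member [TrainedModel-class] objects.
#' @slot tag free label.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  slots = c(memberA = "TrainedModel", memberB = "TrainedModel",
            tag = "character")
)

#' Agreement-metric report
#'
#' @slot accuracyPct mean relative accuracy, percent.
#' @slot mae,sdae,rmse error metrics in bpm (SDAE = population SD of the
#'   absolute errors).
#' @slot cc Pearson correlation of labels and estimates (NA when undefined).
#' @slot n number of pairs.
#' @exportClass EvalReport
setClass("EvalReport",
  slots = c(accuracyPct = "numeric", mae = "numeric", sdae = "numeric",
            rmse = "numeric", cc = "numeric", n = "integer")
)

#' Bland-Altman agreement result
#'
#' @slot meanDiff mean difference (estimate - label), bpm.
#' @slot sdDiff population SD of the differences, bpm.
#' @slot loaLow,loaHigh 95% limits of agreement, mean +/- 1.96 SD.
#' @slot pairs data.frame of per-pair (mean, difference) coordinates.
#' @exportClass BlandAltmanResult
setClass("BlandAltmanResult",
  slots = c(meanDiff = "numeric", sdDiff = "numeric", loaLow = "numeric",
            loaHigh = "numeric", pairs = "data.frame")
)

#' A-Test structural-risk report
#'
#' @slot tauByZ regression error (fold-mean MAE) for each fold count z =
#'   2..zmax.
#' @slot tauHat mean of tauByZ over the zmax - 1 fold counts.
#' @slot tauMin minimum of tauByZ.
#' @slot zmax largest fold count used.
#' @exportClass ATestReport
setClass("ATestReport",
  slots = c(tauByZ = "numeric", tauHat = "numeric", tauMin = "numeric",
            zmax = "integer")
)

setValidity("ATestReport", function(object) {
  msg <- character()
  if (length(object@tauByZ) != object@zmax - 1L)
    msg <- c(msg, "tauByZ must hold one entry per z in 2..zmax")
  if (abs(object@tauHat - sum(object@tauByZ) / (object@zmax - 1L)) > 1e-9)
    msg <- c(msg, "tauHat must be sum(tauByZ)/(zmax - 1)")
  if (length(msg)) msg else TRUE
})
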