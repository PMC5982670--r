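#' @include AllClasses.R nn-engine.R
NULL

# Canonical VGG stage plans (conv channel counts per pooling stage).
VGG_STAGE_PLANS <- list(
  vgg11 = list(64, 128, c(256, 256), c(512, 512), c(512, 512)),
  vgg13 = list(c(64, 64), c(128, 128), c(256, 256), c(512, 512),
               c(512, 512)),
  vgg16 = list(c(64, 64), c(128, 128), c(256, 256, 256),
               c(512, 512, 512), c(512, 512, 512)),
  vgg19 = list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
               c(512, 512, 512, 512), c(512, 512, 512, 512))
)

#' Build a 1-D VGG architecture specification
#'
#' The four depth variants carry 8 (VGG-11), 10 (VGG-13), 13 (VGG-16) and
#' 16 (VGG-19) convolutional layers plus three fully connected layers. All
#' convolutions are 1x3 with rectified-linear activations, each of the five
#' stages ends in 1x2 max-pooling, and the single linear output node
#' regresses heart rate. Stage widths follow the canonical VGG progression
#' (64, 128, 256, 512, 512; hidden FC 4096) scaled by `widthMultiplier`,
#' which changes capacity without changing topology (0.125-0.25 makes
#' CPU-scale training practical).
#'
#' @param variant "vgg11", "vgg13", "vgg16" or "vgg19".
#' @param widthMultiplier scaling on every stage/FC width (default 1).
#' @param inputChannels,inputLength input window geometry (6 x 1280).
#' @param dropoutP dropout probability on the hidden FC layers (0.5).
#' @return a validated [ModelSpec-class].
#' @export
modelSpec <- function(variant = c("vgg11", "vgg13", "vgg16", "vgg19"),
                      widthMultiplier = 1, inputChannels = 6L,
                      inputLength = 1280L, dropoutP = 0.5) {
  variant <- match.arg(variant)
  scale <- function(w) pmax(1L, as.integer(round(w * widthMultiplier)))
  new("ModelSpec", variant = variant,
      stageWidths = lapply(VGG_STAGE_PLANS[[variant]], scale),
      fcWidths = scale(c(4096L, 4096L)), dropoutP = dropoutP,
      widthMultiplier = widthMultiplier,
      inputChannels = as.integer(inputChannels),
      inputLength = as.integer(inputLength))
}

#' Build training hyperparameters
#'
#' Defaults are the reference training settings: Adam at learning rate 1e-4 on the L2
#' loss, 128-sized minibatches, 100 epochs, Xavier initialization. Reduced
#' desk-scale runs typically raise the learning rate and cut the epochs.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param centerOutputBias start the output bias at the mean training label
#'   (default TRUE; weights remain Xavier).
#' @param seed integer seed for init, shuffling and dropout.
#' @return a validated [TrainHyper-class].
#' @export
trainHyper <- function(learningRate = 1e-4, batchSize = 128L,
                       epochs = 100L, centerOutputBias = TRUE, seed = 1L) {
  new("TrainHyper", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      centerOutputBias = centerOutputBias, seed = as.integer(seed))
}

#' Instantiate an untrained network
#'
#' Builds the layer stack of the spec with Xavier-uniform weights and zero
#' biases.
#'
#' @param spec a [ModelSpec-class].
#' @param seed integer seed for the initialization.
#' @return an [HRNet-class].
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  new("HRNet", spec = spec, parameters = initLayers(spec, seed),
      initSeed = as.integer(seed))
}

#' Count convolutional layers of a model
#' @param x an [HRNet-class], [TrainedModel-class] or [ModelSpec-class].
#' @return integer count.
#' @export
convLayerCount <- function(x) {
  layers <- modelLayers(x)
  if (is.null(layers))
    return(sum(lengths(x@stageWidths)))
  sum(vapply(layers, function(l) l$type == "conv", logical(1)))
}

#' Count fully connected layers of a model
#' @inheritParams convLayerCount
#' @return integer count.
#' @export
fcLayerCount <- function(x) {
  layers <- modelLayers(x)
  if (is.null(layers)) return(3L)
  sum(vapply(layers, function(l) l$type == "fc", logical(1)))
}

#' Temporal length of the feature map before flattening
#' @inheritParams convLayerCount
#' @return integer sample count (input length over 2^5).
#' @export
featureMapLength <- function(x) {
  spec <- if (is(x, "ModelSpec")) x else x@spec
  spec@inputLength %/% 32L
}

#' Total trainable parameter count
#' @inheritParams convLayerCount
#' @return integer count of weights and biases.
#' @export
parameterCount <- function(x) {
  layers <- modelLayers(x)
  sum(vapply(layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), integer(1)))
}

modelLayers <- function(x) {
  if (is(x, "ModelSpec")) NULL else x@parameters
}

#' Train a network on a labeled window set
#'
#' Minimizes the mean squared error of predicted versus labeled heart rate
#' over minibatches with Adam, evaluates the validation cost once per
#' epoch, and returns the parameters from the epoch with the lowest
#' validation cost together with the full history.
#'
#' @param model an [HRNet-class] from [buildModel()] (or a
#'   [ModelSpec-class], in which case the network is initialized with the
#'   hyperparameter seed).
#' @param ds a [LabeledWindowSet-class] with non-empty train and validation
#'   splits.
#' @param hyper a [TrainHyper-class].
#' @param tag label stored on the result (e.g. "vgg16_noaug").
#' @return a [TrainedModel-class].
#' @export
trainModel <- function(model, ds, hyper = trainHyper(), tag = NULL) {
  if (is(model, "ModelSpec")) model <- buildModel(model, hyper@seed)
  stopifnot(is(model, "HRNet"), is(ds, "LabeledWindowSet"),
            is(hyper, "TrainHyper"))
  validObject(hyper)
  trIdx <- which(!is.na(ds@split) & ds@split == "train")
  vaIdx <- which(!is.na(ds@split) & ds@split == "validation")
  if (!length(trIdx)) stop("empty train split")
  if (!length(vaIdx)) stop("empty validation split")
  xTr <- flattenWindows(ds@windows[trIdx, , , drop = FALSE])
  xVa <- flattenWindows(ds@windows[vaIdx, , , drop = FALSE])
  fit <- fitLayers(model@parameters, xTr, ds@labels[trIdx], xVa,
                   ds@labels[vaIdx], model@spec, hyper)
  new("TrainedModel", spec = model@spec, hyper = hyper,
      parameters = fit$layers, history = fit$history,
      bestEpoch = fit$bestEpoch,
      tag = if (is.null(tag)) model@spec@variant else tag)
}

predictLayers <- function(spec, layers, windows, split) {
  if (is(windows, "LabeledWindowSet"))
    windows <- windowArray(windows, split)
  stopifnot(length(dim(windows)) == 3L)
  d <- dim(windows)
  if (d[2] != spec@inputChannels || d[3] != spec@inputLength)
    stop(sprintf("window shape %d x %d does not match model input %d x %d",
                 d[2], d[3], spec@inputChannels, spec@inputLength))
  if (d[1] == 0L) return(numeric(0))
  netPredict(layers, flattenWindows(windows), d[1], spec@inputLength)
}

#' @describeIn predictHR single-network prediction (dropout disabled).
#' @export
setMethod("predictHR", "TrainedModel", function(object, windows,
                                                split = "test") {
  predictLayers(object@spec, object@parameters, windows, split)
})

#' @describeIn predictHR ensemble prediction: elementwise mean of the two
#'   member predictions.
#' @export
setMethod("predictHR", "EnsembleModel", function(object, windows,
                                                 split = "test") {
  a <- predictHR(object@memberA, windows, split)
  b <- predictHR(object@memberB, windows, split)
  if (length(a) != length(b))
    stop("ensemble members disagree on window count")
  (a + b) / 2
})

#' Pair two trained networks into an ensemble
#'
#' The recommended configuration pairs a VGG-16 trained without
#' augmentation with a VGG-19 trained with augmentation; prediction is the
#' arithmetic mean of the members.
#'
#' @param memberA,memberB the member [TrainedModel-class] objects.
#' @param tag label for the ensemble.
#' @return an [EnsembleModel-class].
#' @export
ensembleModel <- function(memberA, memberB, tag = "ensemble") {
  stopifnot(is(memberA, "TrainedModel"), is(memberB, "TrainedModel"))
  new("EnsembleModel", memberA = memberA, memberB = memberB, tag = tag)
}

#' Validation cost of a trained model's stored parameters
#'
#' Recomputes the mean squared error of the checkpointed parameters on the
#' validation split; matches the recorded best-epoch cost.
#'
#' @param model a [TrainedModel-class].
#' @param ds the [LabeledWindowSet-class] it was trained on.
#' @return mean squared error in bpm^2.
#' @export
validationCost <- function(model, ds) {
  vaIdx <- which(!is.na(ds@split) & ds@split == "validation")
  x <- flattenWindows(ds@windows[vaIdx, , , drop = FALSE])
  netCost(model@parameters, x, ds@labels[vaIdx], model@spec@inputLength)
}
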