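#' @include AllClasses.R simulate.R preprocess.R augment.R model.R evaluate.R
NULL

#' Default end-to-end run configuration
#'
#' A nested list mirroring the YAML schema of the command-line interface.
#' Every stage seed derives from the single global seed (documented
#' derivation: stage seeds are `seed * 1009 + offset` modulo 2^31, with a
#' distinct offset per stage), so a run is reproducible from `seed` alone.
#'
#' @param seed global integer seed.
#' @return configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(subjects = 2L, durationS = 60, snrDb = 6,
                    conditions = "postures"),
    preprocess = list(targetRate = 256, sgOrder = 2, sgWindow = 31,
                      windowS = 5, strideS = 1, hrMin = 60, hrMax = 200),
    augment = list(enabled = FALSE, copiesPerSample = 1),
    members = list(
      list(variant = "vgg16", augmented = FALSE, tag = "vgg16_noaug"),
      list(variant = "vgg19", augmented = TRUE, tag = "vgg19_aug")),
    train = list(widthMultiplier = 0.125, learningRate = 1e-3,
                 batchSize = 128, epochs = 10),
    evaluate = list(split = "test")
  )
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        is.null(names(override[[k]])) == is.null(names(base[[k]])) &&
        !is.null(names(base[[k]])))
      base[[k]] <- mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full pipeline: simulate, preprocess, train, evaluate
#'
#' Executes simulation of the configured sessions, windowing and split
#' assignment, optional training-set augmentation, member training, ensemble
#' prediction on the held-out split, and evaluation. All artifacts (dataset,
#' models, predictions, reports, manifest) are written under `outDir`; the
#' run is reproducible from the global seed.
#'
#' @param config a configuration list as from [defaultRunConfig()], a path
#'   to a YAML file with the same structure, or NULL for the defaults;
#'   partial configurations are merged over the defaults.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the dataset, models, predictions and the
#'   evaluation report.
#' @export
runEndToEnd <- function(config = NULL, outDir = tempfile("seismohr_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultRunConfig(), if (is.null(config)) list()
                     else config)
  for (m in cfg$members)
    if (!m$variant %in% names(VGG_CONV_COUNTS))
      stop("config validation error: unknown variant '", m$variant, "'")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  # 1. simulate
  specs <- list()
  for (s in seq_len(cfg$simulate$subjects)) {
    subjectSeed <- deriveSeed(seed, 1000L + s)
    conds <- if (identical(cfg$simulate$conditions, "all"))
      standardConditions(cfg$simulate$durationS,
                         subject = sprintf("s%02d", s),
                         seed = subjectSeed, snrDb = cfg$simulate$snrDb)
    else {
      lapply(seq_along(POSTURE_GRID), function(i)
        conditionSpec(posture = POSTURE_GRID[[i]][1],
                      physicalState = POSTURE_GRID[[i]][2],
                      durationS = cfg$simulate$durationS,
                      snrDb = cfg$simulate$snrDb,
                      subject = sprintf("s%02d", s),
                      seed = deriveSeed(subjectSeed, i)))
    }
    specs <- c(specs, conds)
  }
  sessions <- lapply(specs, simulateSession)

  # 2. preprocess
  pp <- cfg$preprocess
  pcfg <- preprocessConfig(targetRate = pp$targetRate, sgOrder = pp$sgOrder,
                           sgWindow = pp$sgWindow, windowS = pp$windowS,
                           strideS = pp$strideS, hrMin = pp$hrMin,
                           hrMax = pp$hrMax)
  ds <- buildDataset(sessions, pcfg, shuffleSeed = deriveSeed(seed, 2L))
  saveDataset(ds, file.path(outDir, "dataset.feather"))

  # 3. augment (training split only)
  dsAug <- if (isTRUE(cfg$augment$enabled) ||
               any(vapply(cfg$members, function(m) isTRUE(m$augmented),
                          logical(1))))
    augmentDataset(ds, augmentationPolicy(
      copiesPerSample = cfg$augment$copiesPerSample,
      seed = deriveSeed(seed, 3L)))
  else ds

  # 4. train members
  models <- list()
  for (i in seq_along(cfg$members)) {
    m <- cfg$members[[i]]
    spec <- modelSpec(m$variant,
                      widthMultiplier = cfg$train$widthMultiplier,
                      inputLength = dim(ds@windows)[3],
                      inputChannels = dim(ds@windows)[2])
    hyper <- trainHyper(learningRate = cfg$train$learningRate,
                        batchSize = cfg$train$batchSize,
                        epochs = cfg$train$epochs,
                        seed = deriveSeed(seed, 10L + i))
    data <- if (isTRUE(m$augmented)) dsAug else ds
    models[[i]] <- trainModel(spec, data, hyper, tag = m$tag)
    saveRDS(models[[i]], file.path(outDir, paste0(m$tag, ".rds")))
    utils::write.csv(models[[i]]@history,
                     file.path(outDir, paste0(m$tag, "_history.csv")),
                     row.names = FALSE)
  }
  predictor <- if (length(models) >= 2L)
    ensembleModel(models[[1]], models[[2]]) else models[[1]]

  # 5. predict + evaluate on the held-out split
  split <- cfg$evaluate$split
  teIdx <- which(!is.na(ds@split) & ds@split == split)
  yTrue <- ds@labels[teIdx]
  yPred <- predictHR(predictor, ds, split = split)
  utils::write.csv(
    data.frame(ds@source[teIdx, , drop = FALSE], label = yTrue,
               estimate = yPred),
    file.path(outDir, "predictions.csv"), row.names = FALSE)
  report <- errorMetrics(yTrue, yPred)
  ba <- blandAltman(yTrue, yPred)
  reportList <- list(
    n = report@n, accuracyPct = report@accuracyPct, mae = report@mae,
    sdae = report@sdae, rmse = report@rmse, cc = report@cc,
    blandAltman = list(meanDiff = ba@meanDiff, sdDiff = ba@sdDiff,
                       loaLow = ba@loaLow, loaHigh = ba@loaHigh))
  jsonlite::write_json(reportList, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "seismoHR",
    version = as.character(utils::packageVersion("seismoHR")),
    rVersion = R.version.string, seed = seed, config = cfg,
    nWindows = nWindows(ds),
    nCandidates = ds@meta$nCandidates, nExcluded = ds@meta$nExcluded)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dataset = ds, models = models, predictor = predictor,
                 yTrue = yTrue, yPred = yPred, report = report,
                 blandAltman = ba, outDir = outDir))
}

POSTURE_GRID <- list(c("sitting", "relaxed"), c("standing", "aroused"))
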