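#' @include AllClasses.R
NULL

#' Build an augmentation policy
#'
#' Defaults are mild, label-safe perturbations in post-normalization units:
#' circular shift drawn uniformly over \[0, n), Gaussian-noise SD drawn
#' uniformly from \[0.05, 0.2\], scaling ratio drawn uniformly from
#' \[-0.1, 0.1\], and one augmented copy per training window (doubling the
#' training set).
#'
#' @param permAlpha fixed integer shift for the permutation operator, or NA
#'   (default) to draw uniformly per copy.
#' @param jitterRange range (or single value) for the jitter SD.
#' @param scaleRange range (or single value) for the scaling ratio.
#' @param copiesPerSample augmented copies per training window.
#' @param seed integer seed for the per-copy draws.
#' @return a validated [AugmentationPolicy-class].
#' @export
augmentationPolicy <- function(permAlpha = NA_integer_,
                               jitterRange = c(0.05, 0.2),
                               scaleRange = c(-0.1, 0.1),
                               copiesPerSample = 1L, seed = 1L) {
  if (length(jitterRange) == 1L) jitterRange <- rep(jitterRange, 2L)
  if (length(scaleRange) == 1L) scaleRange <- rep(scaleRange, 2L)
  new("AugmentationPolicy", permAlpha = as.integer(permAlpha),
      jitterRange = jitterRange, scaleRange = scaleRange,
      copiesPerSample = as.integer(copiesPerSample),
      seed = as.integer(seed))
}

#' Permutation: circular shift of the temporal location
#'
#' Rotates each channel right by `alpha` samples: output element i is
#' `x[n - alpha + i]` for i < alpha and `x[i - alpha]` otherwise (0-based),
#' with the same shift applied to every channel of a window. The per-channel
#' sample multiset is preserved exactly, so the heart-rate label is
#' unchanged.
#'
#' @param x numeric vector (one channel) or channels-by-samples matrix.
#' @param alpha integer shift in \[0, n).
#' @return the shifted window, same shape.
#' @export
permuteWindow <- function(x, alpha) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (alpha < 0 || alpha >= n) stop("alpha out of range [0, n)")
  if (alpha == 0) return(x)
  idx <- c((n - alpha + 1L):n, 1L:(n - alpha))
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
}

#' Jittering: additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with SD `alpha` to every element.
#' `alpha = 0` returns the input exactly.
#'
#' @param x numeric vector or matrix window.
#' @param alpha noise SD (post-normalization units), `>= 0`.
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return the jittered window, same shape.
#' @export
jitterWindow <- function(x, alpha, seed = NULL) {
  if (alpha < 0) stop("negative noise SD")
  if (alpha == 0) return(x)
  noise <- if (is.null(seed)) stats::rnorm(length(x), sd = alpha)
           else withSeed(seed, stats::rnorm(length(x), sd = alpha))
  x + noise
}

#' Scaling: amplitude change by a fixed ratio
#'
#' Multiplies the window elementwise by `(1 + alpha)`.
#'
#' @param x numeric vector or matrix window.
#' @param alpha scaling ratio, `> -1`.
#' @return the scaled window, same shape.
#' @export
scaleWindow <- function(x, alpha) {
  if (alpha <= -1) stop("scaling ratio must be > -1")
  x * (1 + alpha)
}

#' Expand the training split by composed augmentation
#'
#' For every training window, `copiesPerSample` new windows are emitted;
#' each copy applies scaling, then jittering, then permutation, with
#' per-copy parameters drawn from the policy ranges (fixed order for
#' reproducibility; the order does not affect label preservation). Labels
#' are copied unchanged and validation/test windows are never augmented.
#'
#' @param ds a [LabeledWindowSet-class] with split tags assigned.
#' @param policy an [AugmentationPolicy-class].
#' @return the expanded [LabeledWindowSet-class]; augmented windows carry
#'   `augmented = TRUE` in their provenance rows.
#' @export
augmentDataset <- function(ds, policy = augmentationPolicy()) {
  stopifnot(is(ds, "LabeledWindowSet"), is(policy, "AugmentationPolicy"))
  validObject(policy)
  if (policy@copiesPerSample == 0L) return(ds)
  trainIdx <- which(!is.na(ds@split) & ds@split == "train")
  d <- dim(ds@windows)
  nSamp <- d[3]
  nNew <- length(trainIdx) * policy@copiesPerSample
  if (nNew == 0L) return(ds)
  newWin <- array(0, dim = c(nNew, d[2], nSamp))
  newLab <- numeric(nNew)
  newSrcIdx <- integer(nNew)
  withSeed(policy@seed, {
    k <- 0L
    for (i in trainIdx) for (cp in seq_len(policy@copiesPerSample)) {
      k <- k + 1L
      w <- ds@windows[i, , ]
      w <- scaleWindow(w, stats::runif(1, policy@scaleRange[1],
                                       policy@scaleRange[2]))
      w <- jitterWindow(w, stats::runif(1, policy@jitterRange[1],
                                        policy@jitterRange[2]))
      alpha <- if (is.na(policy@permAlpha))
        sample.int(nSamp, 1L) - 1L else policy@permAlpha
      newWin[k, , ] <- permuteWindow(w, alpha)
      newLab[k] <- ds@labels[i]
      newSrcIdx[k] <- i
    }
  })
  src <- ds@source
  if (!"augmented" %in% names(src)) src$augmented <- FALSE
  newSrc <- src[newSrcIdx, , drop = FALSE]
  newSrc$augmented <- TRUE
  rownames(newSrc) <- NULL
  all <- array(0, dim = c(d[1] + nNew, d[2], nSamp))
  all[seq_len(d[1]), , ] <- ds@windows
  all[d[1] + seq_len(nNew), , ] <- newWin
  new("LabeledWindowSet", windows = all,
      labels = c(ds@labels, newLab),
      split = c(ds@split, rep("train", nNew)),
      source = rbind(src, newSrc),
      splitFractions = ds@splitFractions, shuffleSeed = ds@shuffleSeed,
      channelNames = ds@channelNames, sampleRate = ds@sampleRate,
      meta = c(ds@meta, list(augmentation = policy)))
}
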