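#' @include AllClasses.R ecg-label.R
NULL

#' Build a preprocessing configuration
#'
#' Defaults follow the reference pipeline: cubic-spline resampling to 256 Hz,
#' Savitzky-Golay trend subtraction (order 2, window 31 samples, about
#' 121 ms), zero-mean/unit-variance normalization per channel per window,
#' 5 s windows at a 1 s stride, and exclusion of labels outside 60-200 bpm.
#'
#' @param targetRate resampling rate in Hz.
#' @param sgOrder,sgWindow Savitzky-Golay polynomial order and (odd) window.
#' @param windowS,strideS sliding-window length and stride in seconds.
#' @param hrMin,hrMax label keep-range in bpm.
#' @param normalizeScope "window" (default) or "recording".
#' @return a validated [PreprocessConfig-class].
#' @export
preprocessConfig <- function(targetRate = 256, sgOrder = 2L, sgWindow = 31L,
                             windowS = 5, strideS = 1, hrMin = 60,
                             hrMax = 200, normalizeScope = "window") {
  new("PreprocessConfig", targetRate = targetRate,
      sgOrder = as.integer(sgOrder), sgWindow = as.integer(sgWindow),
      windowS = windowS, strideS = strideS, hrMin = hrMin, hrMax = hrMax,
      normalizeScope = normalizeScope)
}

#' Resample a recording onto a uniform grid by cubic splines
#'
#' Fits a cubic spline through the original (possibly irregular) samples of
#' each channel and evaluates it on a uniform grid at `targetRate` spanning
#' \[first, last\] timestamp. Channel order is preserved. The "fmm" end
#' condition is used, so any cubic polynomial is reproduced exactly.
#'
#' @param rec a [MultichannelRecording-class] with at least 4 samples.
#' @param targetRate grid rate in Hz.
#' @return the resampled [MultichannelRecording-class].
#' @export
resampleCubic <- function(rec, targetRate = 256) {
  stopifnot(is(rec, "MultichannelRecording"))
  ts <- rec@timestamps
  if (length(ts) < 4L) stop("need at least 4 samples for cubic resampling")
  if (anyDuplicated(ts)) stop("duplicate timestamps")
  grid <- seq(ts[1], ts[length(ts)], by = 1 / targetRate)
  out <- matrix(0, nrow = length(grid), ncol = ncol(rec@values))
  for (ch in seq_len(ncol(out)))
    out[, ch] <- stats::spline(ts, rec@values[, ch], xout = grid,
                               method = "fmm")$y
  multichannelRecording(grid, out, channelNames = rec@channelNames,
                        nominalRate = targetRate,
                        meta = c(rec@meta, list(resampledTo = targetRate)))
}

# Centre-point Savitzky-Golay smoothing weights for a symmetric window of
# half-width m and polynomial order `order`: the centre row of the
# least-squares projection matrix.
sgCenterWeights <- function(order, window) {
  m <- (window - 1L) / 2L
  A <- outer(seq(-m, m), 0:order, `^`)
  P <- A %*% solve(crossprod(A), t(A))
  P[m + 1L, ]
}

#' Savitzky-Golay trend of a uniformly sampled signal
#'
#' Each interior point is the centre value of a least-squares polynomial of
#' the given order fitted over the centred window. At the edges, where the
#' centred window does not fit, the polynomial is fitted on the one-sided
#' truncated window (no data is fabricated by padding) and evaluated at the
#' point.
#'
#' @param x numeric vector (one uniformly sampled channel), `length(x) >=
#'   window`.
#' @param order polynomial order (default 2).
#' @param window odd window length in samples (default 31).
#' @return the trend, same length as `x`.
#' @seealso [removeMotion()]
#' @export
sgTrend <- function(x, order = 2L, window = 31L) {
  n <- length(x)
  if (window %% 2L == 0L || window <= order)
    stop("window must be odd and greater than order")
  if (n < window) stop("signal shorter than the filter window")
  m <- (window - 1L) / 2L
  w <- sgCenterWeights(order, window)
  trend <- as.numeric(stats::filter(x, rev(w), sides = 2))
  # one-sided truncated-window fits at the edges
  for (i in seq_len(m)) {
    idx <- 1L:(i + m)
    fit <- stats::lm.fit(outer(idx - i, 0:order, `^`), x[idx])
    trend[i] <- fit$coefficients[1]
    idx <- (n - i - m + 1L):n
    j <- n - i + 1L
    fit <- stats::lm.fit(outer(idx - j, 0:order, `^`), x[idx])
    trend[j] <- fit$coefficients[1]
  }
  trend
}

#' Remove large-range motion by Savitzky-Golay subtraction
#'
#' The motion-induced trend is estimated by [sgTrend()] and subtracted,
#' leaving the cardiac micro-vibrations. The operation is linear.
#'
#' @inheritParams sgTrend
#' @return the detrended signal, same length as `x`.
#' @export
removeMotion <- function(x, order = 2L, window = 31L) {
  x - sgTrend(x, order = order, window = window)
}

#' Normalize a signal to zero mean and unit variance
#'
#' Population (1/n) variance convention, so the result is exactly
#' idempotent.
#'
#' @param x numeric vector; must not be constant.
#' @param channel channel name used in the error message for constant
#'   input.
#' @return the normalized signal.
#' @export
zNormalize <- function(x, channel = "signal") {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v == 0)
    stop(sprintf("constant signal (zero variance) in channel '%s'", channel))
  (x - mu) / sqrt(v)
}

#' Cut a paired recording into fixed-size labeled windows
#'
#' End-to-end window construction: the motion recording is resampled to the
#' target rate by cubic splines, each channel is Savitzky-Golay detrended,
#' the ECG is labeled by Pan-Tompkins QRS detection, and 5 s windows at a
#' 1 s stride are cut from the common time span of the two recordings
#' (fractional-sample ends truncated). Each window carries exactly
#' `windowS * targetRate` samples per channel, is normalized per channel
#' (per window by default), and is labeled with 60/mean(RR) over the RR
#' intervals wholly inside its span. Windows with undefined labels or
#' labels outside \[hrMin, hrMax\] are dropped; the candidate and excluded
#' counts are kept in the result's `meta`.
#'
#' @param motion six-channel [MultichannelRecording-class] (or a
#'   [SimulatedSession-class], in which case `ecg` is taken from it).
#' @param ecg single-channel ECG [MultichannelRecording-class].
#' @param cfg a [PreprocessConfig-class].
#' @return a [LabeledWindowSet-class] with unassigned split tags.
#' @export
windowize <- function(motion, ecg = NULL, cfg = preprocessConfig()) {
  if (is(motion, "SimulatedSession")) {
    ecg <- motion@ecg
    motion <- motion@motion
  }
  stopifnot(is(motion, "MultichannelRecording"),
            is(ecg, "MultichannelRecording"), is(cfg, "PreprocessConfig"))
  validObject(cfg)
  winN <- as.integer(round(cfg@windowS * cfg@targetRate))
  rs <- resampleCubic(motion, cfg@targetRate)
  det <- rs@values
  for (ch in seq_len(ncol(det)))
    det[, ch] <- removeMotion(det[, ch], cfg@sgOrder, cfg@sgWindow)
  if (cfg@normalizeScope == "recording")
    for (ch in seq_len(ncol(det)))
      det[, ch] <- zNormalize(det[, ch], rs@channelNames[ch])

  peaks <- detectRPeaks(ecg)
  grid <- rs@timestamps
  tStart <- max(grid[1], ecg@timestamps[1])
  tEnd <- min(grid[length(grid)], ecg@timestamps[length(ecg@timestamps)])
  span <- tEnd - tStart
  if (span < cfg@windowS)
    stop(sprintf("common time span (%.2f s) shorter than the window (%g s)",
                 span, cfg@windowS))
  # windows start at the first grid point at/after the common start and
  # advance by the stride; K = floor((T - window)/stride) + 1
  i0 <- which(grid >= tStart - 1e-9)[1]
  strideN <- cfg@strideS * cfg@targetRate
  if (abs(strideN - round(strideN)) > 1e-9)
    stop("strideS x targetRate must be an integer sample count")
  strideN <- as.integer(round(strideN))
  K <- floor((span - cfg@windowS) / cfg@strideS + 1e-9) + 1L
  # never read past the resampled grid
  K <- as.integer(min(K, (length(grid) - i0 + 1L - winN) %/% strideN + 1L))
  if (K < 1L) stop("no complete window fits the common span")

  windows <- array(0, dim = c(K, ncol(det), winN))
  labels <- numeric(K)
  starts <- numeric(K)
  keep <- logical(K)
  for (k in seq_len(K)) {
    a <- i0 + (k - 1L) * strideN
    idx <- a:(a + winN - 1L)
    ws <- grid[a]
    hr <- heartRateFromWindow(peaks, ws, ws + cfg@windowS)
    starts[k] <- ws
    if (is.na(hr) || hr < cfg@hrMin || hr > cfg@hrMax) next
    w <- t(det[idx, , drop = FALSE])
    if (cfg@normalizeScope == "window")
      for (ch in seq_len(nrow(w)))
        w[ch, ] <- zNormalize(w[ch, ], rs@channelNames[ch])
    windows[k, , ] <- w
    labels[k] <- hr
    keep[k] <- TRUE
  }
  m <- motion@meta
  condition <- if (!is.null(m$speedKmh) && m$speedKmh > 0)
    sprintf("speed_%g", m$speedKmh)
  else if (!is.null(m$posture))
    sprintf("%s_%s", m$posture, m$physicalState)
  else "unknown"
  src <- data.frame(
    subject = rep(if (is.null(m$subject)) "unknown" else m$subject, K),
    condition = rep(condition, K),
    windowStart = starts, stringsAsFactors = FALSE)
  new("LabeledWindowSet",
      windows = windows[keep, , , drop = FALSE], labels = labels[keep],
      split = rep(NA_character_, sum(keep)),
      source = src[keep, , drop = FALSE],
      splitFractions = c(0.7, 0.1, 0.2), shuffleSeed = NA_integer_,
      channelNames = rs@channelNames, sampleRate = cfg@targetRate,
      meta = list(nCandidates = K, nExcluded = as.integer(K - sum(keep)),
                  config = cfg))
}

#' Pool windowed sessions and assign the train/validation/test split
#'
#' Windows from all sessions are pooled, shuffled with the stated seed, and
#' sliced 70/10/20 (counts `round(0.70 n)`, `round(0.10 n)`, remainder), so
#' the assignment is reproducible. Optionally the split can instead be
#' grouped by subject, keeping each subject's windows in a single split
#' (addresses subject leakage; not the default, which reproduces the plain
#' shuffled split).
#'
#' @param sessions list of [SimulatedSession-class] objects or of
#'   [LabeledWindowSet-class] objects already produced by [windowize()].
#' @param cfg a [PreprocessConfig-class] (used when sessions still need
#'   windowing).
#' @param shuffleSeed integer seed for the shuffle.
#' @param splitFractions train/validation/test fractions (default 0.70,
#'   0.10, 0.20).
#' @param bySubject if TRUE, use the subject-grouped split.
#' @return a [LabeledWindowSet-class] with split tags assigned.
#' @export
buildDataset <- function(sessions, cfg = preprocessConfig(),
                         shuffleSeed = 1L,
                         splitFractions = c(0.7, 0.1, 0.2),
                         bySubject = FALSE) {
  if (is(sessions, "SimulatedSession") || is(sessions, "LabeledWindowSet"))
    sessions <- list(sessions)
  sets <- lapply(sessions, function(s)
    if (is(s, "LabeledWindowSet")) s else windowize(s, cfg = cfg))
  nPer <- vapply(sets, nWindows, integer(1))
  n <- sum(nPer)
  if (n < 10L) stop("too few windows (", n, ") to split")
  d3 <- dim(sets[[1]]@windows)[3]
  windows <- array(0, dim = c(n, dim(sets[[1]]@windows)[2], d3))
  labels <- numeric(n)
  source <- do.call(rbind, lapply(sets, function(s) s@source))
  at <- 0L
  for (s in sets) {
    k <- nWindows(s)
    if (k) windows[at + seq_len(k), , ] <- s@windows
    labels[at + seq_len(k)] <- s@labels
    at <- at + k
  }
  split <- rep(NA_character_, n)
  if (bySubject) {
    subj <- source$subject
    withSeed(shuffleSeed, {
      us <- sample(unique(subj))
      target <- splitFractions * n
      got <- c(0, 0, 0)
      lab <- c("train", "validation", "test")
      for (s in us) {
        k <- sum(subj == s)
        slot <- which.max((target - got) / pmax(target, 1))
        split[subj == s] <- lab[slot]
        got[slot] <- got[slot] + k
      }
    })
  } else {
    ord <- withSeed(shuffleSeed, sample.int(n))
    nTrain <- round(splitFractions[1] * n)
    nVal <- round(splitFractions[2] * n)
    split[ord[seq_len(nTrain)]] <- "train"
    split[ord[nTrain + seq_len(nVal)]] <- "validation"
    split[ord[(nTrain + nVal + 1L):n]] <- "test"
  }
  meta <- list(
    nCandidates = as.integer(sum(vapply(sets, function(s)
      as.numeric(s@meta$nCandidates %||% nWindows(s)), numeric(1)))),
    nExcluded = as.integer(sum(vapply(sets, function(s)
      as.numeric(s@meta$nExcluded %||% 0), numeric(1)))),
    bySubject = bySubject)
  new("LabeledWindowSet", windows = windows, labels = labels,
      split = split, source = source, splitFractions = splitFractions,
      shuffleSeed = as.integer(shuffleSeed),
      channelNames = sets[[1]]@channelNames,
      sampleRate = sets[[1]]@sampleRate, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
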