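#' @include AllClasses.R
NULL

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic QRS detection stages: 5-15 Hz band-pass (zero-phase Butterworth),
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' adaptive dual thresholds with search-back over the integrated signal.
#' Candidate peaks are refined to the extremum of the band-passed signal and
#' a 200 ms physiological refractory period is enforced. All thresholds
#' adapt to the signal level, so detections are invariant to amplitude
#' scaling.
#'
#' @param ecg single-channel [MultichannelRecording-class] at a fixed rate
#'   of at least 128 Hz.
#' @param refractoryS minimum gap between accepted peaks (default 0.2 s).
#' @param integrationS moving-window integration width (default 0.15 s).
#' @param thrFactor fraction of the signal-noise gap used for the primary
#'   threshold (default 0.25; search-back uses half the primary threshold).
#' @return an [RPeakSeries-class]; a flat or peak-free signal yields an
#'   empty series, not an error.
#' @export
detectRPeaks <- function(ecg, refractoryS = 0.2, integrationS = 0.15,
                         thrFactor = 0.25) {
  stopifnot(is(ecg, "MultichannelRecording"))
  if (ncol(ecg@values) != 1L)
    stop("expected a single-channel ECG recording")
  fs <- ecg@nominalRate
  if (fs < 128) stop("sampling rate must be at least 128 Hz")
  x <- ecg@values[, 1]
  n <- length(x)
  if (n / fs < 3) stop("too-short signal (< 3 s)")
  emptySeries <- function(meta) new("RPeakSeries", peakTimes = numeric(0),
                                    detectionMeta = meta)
  meta <- list(fs = fs, refractoryS = refractoryS,
               integrationS = integrationS, thrFactor = thrFactor)
  if (stats::sd(x) == 0) return(emptySeries(meta))

  # band-pass 5-15 Hz, zero phase so QRS timing is preserved
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  # centred five-point derivative, squaring, moving-window integration
  der <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  mwiN <- max(1L, round(integrationS * fs))
  mwi <- stats::filter(sq, rep(1 / mwiN, mwiN), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks: local maxima of the integrated signal, greedily thinned
  # to the refractory spacing
  isMax <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE) & mwi > 0
  cand <- which(isMax)
  if (!length(cand)) return(emptySeries(meta))
  ord <- cand[order(mwi[cand], decreasing = TRUE)]
  refN <- round(refractoryS * fs)
  keep <- logical(n)
  taken <- logical(n)
  for (i in ord) {
    if (!taken[i]) {
      keep[i] <- TRUE
      taken[max(1L, i - refN + 1L):min(n, i + refN - 1L)] <- TRUE
    }
  }
  cand <- which(keep)

  # adaptive dual-threshold pass with search-back
  spki <- 0.7 * stats::quantile(mwi[cand], 0.9, names = FALSE)
  npki <- 0.5 * stats::median(mwi[cand])
  thr1 <- function() npki + thrFactor * (spki - npki)
  qrs <- integer(0)
  pending <- integer(0)    # sub-threshold candidates for search-back
  for (i in cand) {
    p <- mwi[i]
    srchBack <- FALSE
    if (length(qrs) >= 2) {
      rrAvg <- mean(diff(utils::tail(qrs, 8L))) / fs
      srchBack <- (i - qrs[length(qrs)]) / fs > 1.66 * rrAvg
    }
    if (srchBack && length(pending)) {
      back <- pending[mwi[pending] > 0.5 * thr1()]
      if (length(back)) {
        j <- back[which.max(mwi[back])]
        qrs <- sort(c(qrs, j))
        spki <- 0.25 * mwi[j] + 0.75 * spki
        pending <- integer(0)
      }
    }
    if (p > thr1()) {
      qrs <- c(qrs, i)
      pending <- integer(0)
      spki <- 0.125 * p + 0.875 * spki
    } else {
      pending <- c(pending, i)
      npki <- 0.125 * p + 0.875 * npki
    }
  }
  if (!length(qrs)) return(emptySeries(meta))

  # refine each detection to the band-passed extremum nearby
  half <- round(0.10 * fs)
  peaks <- vapply(qrs, function(i) {
    lo <- max(1L, as.integer(i - half))
    hi <- min(n, as.integer(i + half))
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory constraint on the final times (keep the taller)
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if ((p - out[length(out)]) / fs >= refractoryS) out <- c(out, p)
      else if (abs(bp[p]) > abs(bp[out[length(out)]]))
        out[length(out)] <- p
    }
    peaks <- out
  }
  meta$spki <- spki
  meta$npki <- npki
  new("RPeakSeries", peakTimes = ecg@timestamps[peaks],
      detectionMeta = meta)
}

#' Heart rate of a window from detected R peaks
#'
#' The label is 60 over the mean of the RR intervals whose *both* endpoints
#' fall inside the window; intervals spanning a window edge are excluded.
#' With fewer than two peaks inside the window the label is undefined and
#' `NA` is returned (such windows are dropped upstream).
#'
#' @param peaks an [RPeakSeries-class].
#' @param t0,t1 window bounds in seconds (a 5 s window in the standard
#'   pipeline).
#' @return heart rate in bpm, or `NA_real_` when undefined.
#' @export
heartRateFromWindow <- function(peaks, t0, t1) {
  stopifnot(is(peaks, "RPeakSeries"), t1 > t0)
  inWin <- peaks@peakTimes[peaks@peakTimes >= t0 & peaks@peakTimes <= t1]
  if (length(inWin) < 2L) return(NA_real_)
  60 / mean(diff(inWin))
}
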