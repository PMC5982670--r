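#' @include AllClasses.R utils.R
NULL

#' Build a measurement-condition specification
#'
#' Constructs the description of one synthetic session. When no heart-rate
#' profile is given, one is drawn (seeded) from the physical-state range:
#' relaxed sessions wander within 60-90 bpm, aroused within 100-180 bpm,
#' as a constant base plus a slow sinusoidal drift.
#'
#' @param posture "sitting", "standing" or "supine".
#' @param physicalState "relaxed" or "aroused".
#' @param speedKmh 0 for a posture condition, or one of 3.2, 4.5, 5.8, 6.4,
#'   8.5, 10.3 (treadmill speeds; performed standing).
#' @param durationS session duration in seconds.
#' @param hrBpm target heart-rate trajectory in bpm: a constant, or a vector
#'   of knots paired with `hrTime`. Must stay in \[40, 220\] (wider than the
#'   60-200 bpm keep-range, so the exclusion rule can be exercised).
#' @param hrTime knot times for `hrBpm` (defaults to an even spacing over
#'   the session).
#' @param snrDb cardiac-pulse-to-interference power ratio in dB (default 6).
#' @param rrJitterCv coefficient of variation of RR-interval jitter
#'   (default 0.02).
#' @param subject subject id for provenance.
#' @param seed integer seed for the session.
#' @return a validated [ConditionSpec-class].
#' @export
conditionSpec <- function(posture = "sitting", physicalState = "relaxed",
                          speedKmh = 0, durationS = 180, hrBpm = NULL,
                          hrTime = NULL, snrDb = 6, rrJitterCv = 0.02,
                          subject = "s01", seed = 1L) {
  if (is.null(hrBpm)) {
    rng <- if (physicalState == "relaxed") c(60, 90) else c(100, 180)
    hrBpm <- withSeed(deriveSeed(seed, 11L), {
      base <- stats::runif(1, rng[1] + 5, rng[2] - 5)
      tt <- seq(0, durationS, length.out = max(8L, ceiling(durationS / 15)))
      ph <- stats::runif(1, 0, 2 * pi)
      pmin(pmax(base + 5 * sin(2 * pi * tt / durationS + ph),
                rng[1]), rng[2])
    })
    hrTime <- seq(0, durationS, length.out = length(hrBpm))
  }
  if (is.null(hrTime)) {
    hrTime <- if (length(hrBpm) == 1L) 0
              else seq(0, durationS, length.out = length(hrBpm))
  }
  new("ConditionSpec", posture = posture, physicalState = physicalState,
      speedKmh = speedKmh, durationS = durationS,
      hrTime = as.numeric(hrTime), hrBpm = as.numeric(hrBpm),
      snrDb = snrDb, rrJitterCv = rrJitterCv, subject = subject,
      seed = as.integer(seed))
}

#' Generate beat (R-peak) times for a heart-rate profile
#'
#' Successive beat gaps equal the instantaneous RR interval 60/hr(t) times a
#' seeded multiplicative jitter with the given coefficient of variation.
#' The first beat falls at t = 0 (within one mean RR of the start); beats
#' are emitted until the duration is exhausted.
#'
#' @param hrBpm heart-rate trajectory in bpm (constant or knot vector).
#' @param durationS duration in seconds.
#' @param seed integer seed for the jitter draws.
#' @param hrTime knot times for `hrBpm` (default even spacing).
#' @param jitterCv coefficient of variation of the RR jitter (0 = none).
#' @return numeric vector of beat times in \[0, durationS\].
#' @export
makeBeatTimes <- function(hrBpm, durationS, seed = 1L, hrTime = NULL,
                          jitterCv = 0.02) {
  if (durationS <= 0) stop("duration must be positive")
  if (any(hrBpm <= 0)) stop("non-positive heart-rate value")
  if (is.null(hrTime))
    hrTime <- if (length(hrBpm) == 1L) 0
              else seq(0, durationS, length.out = length(hrBpm))
  withSeed(seed, {
    beats <- numeric(0)
    t <- 0
    while (t <= durationS) {
      beats <- c(beats, t)
      rr <- 60 / hrAt(hrTime, hrBpm, t)
      g <- if (jitterCv > 0) rr * (1 + jitterCv * stats::rnorm(1)) else rr
      g <- max(g, 0.25 * rr)   # guard against pathological jitter draws
      t <- t + g
    }
    beats
  })
}

#' Render a synthetic single-lead ECG from beat times
#'
#' Each beat places a stereotyped QRS-like complex (narrow biphasic spike,
#' ~80 ms wide, template maximum exactly at the beat time) plus low-amplitude
#' P and T bumps; white Gaussian sensor noise is added on top. Samples run
#' from t = 0 to at least `durationS` at the fixed rate `fs`.
#'
#' @param beatTimes beat times in seconds, within \[0, durationS\].
#' @param durationS recording duration in seconds.
#' @param fs sampling rate in Hz (default 512).
#' @param seed integer seed for the noise.
#' @param noiseSd white-noise SD relative to the unit R-peak (default 0.02).
#' @param amplitude template scaling (R peak height).
#' @return a single-channel [MultichannelRecording-class] named `ecg`.
#' @export
simulateEcg <- function(beatTimes, durationS, fs = 512, seed = 1L,
                        noiseSd = 0.02, amplitude = 1) {
  if (fs <= 0) stop("fs must be positive")
  if (length(beatTimes) && (min(beatTimes) < 0 || max(beatTimes) > durationS))
    stop("beat times must lie within [0, duration]")
  n <- ceiling(durationS * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  x <- withSeed(deriveSeed(seed, 23L),
                stats::rnorm(n, sd = noiseSd * abs(amplitude)))
  addBump <- function(x, center, width, amp) {
    i0 <- max(1L, floor((center - 4 * width) * fs) + 1L)
    i1 <- min(n, ceiling((center + 4 * width) * fs) + 1L)
    if (i0 > i1) return(x)
    idx <- i0:i1
    x[idx] <- x[idx] + amp * exp(-((t[idx] - center) / width)^2)
    x
  }
  nb <- length(beatTimes)
  for (k in seq_len(nb)) {
    tb <- beatTimes[k]
    # P/T offsets shorten with the local RR interval, as the PQ and QT
    # segments do physiologically, so complexes stay separated at high rates
    rrNext <- if (k < nb) beatTimes[k + 1L] - tb else 0.8
    rrPrev <- if (k > 1L) tb - beatTimes[k - 1L] else 0.8
    tOff <- min(0.250, 0.50 * rrNext)
    pOff <- min(0.160, 0.35 * rrPrev)
    tWid <- min(0.060, 0.12 * rrNext)
    x <- addBump(x, tb, 0.012, amplitude)                 # R spike
    x <- addBump(x, tb + 0.028, 0.014, -0.30 * amplitude) # S trough
    x <- addBump(x, tb - 0.025, 0.012, -0.15 * amplitude) # Q trough
    x <- addBump(x, tb - pOff, 0.035, 0.10 * amplitude)   # P wave
    x <- addBump(x, tb + tOff, tWid, 0.20 * amplitude)    # T wave
  }
  multichannelRecording(t, matrix(x, ncol = 1), channelNames = "ecg",
                        nominalRate = fs,
                        meta = list(kind = "ecg", fs = fs))
}

# Default step-frequency map for the treadmill speeds (Hz), from standard
# human cadence ranges; amplitudes of the gait fundamental grow with speed.
GAIT_STEP_HZ <- c(`3.2` = 1.7, `4.5` = 1.9, `5.8` = 2.1,
                  `6.4` = 2.5, `8.5` = 2.8, `10.3` = 3.0)

#' Render six-axis chest motion locked to beat times
#'
#' Each channel sums (a) a cardiac micro-vibration component: one damped
#' oscillation per beat (10-30 Hz carrier, ~150 ms envelope) with a
#' per-channel gain and carrier; (b) an interference component: gait
#' harmonics at the step frequency of the condition's treadmill speed (plus
#' two harmonics, random phases) for speed conditions, or slow (< 0.5 Hz)
#' baseline drift for posture conditions; and (c) white sensor noise. The
#' interference-plus-noise mix is rescaled per channel so that the
#' cardiac-to-interference power ratio equals `snrDb` of the spec. The
#' sampling rate is drawn uniformly from \[100, 200\] Hz per session.
#'
#' @param beatTimes beat times in seconds.
#' @param spec a [ConditionSpec-class].
#' @param cardiacGain overall gain on the cardiac component (0 silences it,
#'   in which case no SNR rescaling is possible and the interference is left
#'   at unit scale).
#' @param drift include baseline drift in posture conditions (default TRUE).
#' @return a six-channel [MultichannelRecording-class].
#' @export
simulateMotion <- function(beatTimes, spec, cardiacGain = 1, drift = TRUE) {
  stopifnot(is(spec, "ConditionSpec"))
  validObject(spec)
  durationS <- spec@durationS
  withSeed(deriveSeed(spec@seed, 37L), {
    fs <- stats::runif(1, 100, 200)
    n <- ceiling(durationS * fs) + 1L
    t <- (seq_len(n) - 1L) / fs
    values <- matrix(0, nrow = n, ncol = 6L)
    envLen <- 0.15                      # s, cardiac pulse envelope support
    for (ch in 1:6) {
      fc <- stats::runif(1, 10, 30)     # carrier within the SCG band
      phi <- stats::runif(1, 0, 2 * pi)
      gain <- stats::runif(1, 0.6, 1.4)
      tau <- 0.04                       # s, envelope decay
      cardiac <- numeric(n)
      for (tb in beatTimes) {
        i0 <- max(1L, floor(tb * fs) + 1L)
        i1 <- min(n, ceiling((tb + envLen) * fs) + 1L)
        if (i0 > i1) next
        dt <- t[i0:i1] - tb
        ok <- dt >= 0
        cardiac[i0:i1][ok] <- cardiac[i0:i1][ok] +
          gain * exp(-dt[ok] / tau) * sin(2 * pi * fc * dt[ok] + phi)
      }
      cardiac <- cardiacGain * cardiac
      if (spec@speedKmh > 0) {
        fstep <- GAIT_STEP_HZ[[as.character(spec@speedKmh)]]
        ampBase <- 1 + 0.15 * (spec@speedKmh - SPEEDS_KMH[1])
        interference <- numeric(n)
        for (k in 1:3) {
          ph <- stats::runif(1, 0, 2 * pi)
          interference <- interference +
            ampBase * c(1, 0.5, 0.25)[k] * sin(2 * pi * k * fstep * t + ph)
        }
      } else if (drift) {
        interference <- numeric(n)
        for (k in 1:3) {
          fd <- stats::runif(1, 0.05, 0.45)
          ph <- stats::runif(1, 0, 2 * pi)
          am <- stats::runif(1, 0.3, 1)
          interference <- interference + am * sin(2 * pi * fd * t + ph)
        }
      } else {
        interference <- numeric(n)
      }
      noise <- stats::rnorm(n)
      pInt <- mean(interference^2)
      # white noise carries ~20% of the interference power (or all of it
      # when there is no structured interference)
      noise <- if (pInt > 0) noise * sqrt(0.25 * pInt) else noise
      interference <- interference + noise
      pCard <- mean(cardiac^2)
      pInt <- mean(interference^2)
      if (pCard > 0 && pInt > 0) {
        target <- pCard / 10^(spec@snrDb / 10)
        interference <- interference * sqrt(target / pInt)
      }
      values[, ch] <- cardiac + interference
    }
    multichannelRecording(
      t, values, channelNames = MOTION_CHANNELS, nominalRate = fs,
      meta = list(kind = "motion", fs = fs, posture = spec@posture,
                  physicalState = spec@physicalState,
                  speedKmh = spec@speedKmh, subject = spec@subject,
                  snrDb = spec@snrDb, seed = spec@seed))
  })
}

#' Simulate one paired chest-motion/ECG session
#'
#' Draws beat times from the spec's heart-rate profile, then renders the ECG
#' (512 Hz) and the six-axis motion recording from the same beats, so the
#' ground truth is shared exactly. Both recordings cover at least
#' `durationS` seconds.
#'
#' @param spec a [ConditionSpec-class].
#' @param cardiacGain,drift passed to [simulateMotion()].
#' @param ecgNoiseSd passed to [simulateEcg()].
#' @return a [SimulatedSession-class].
#' @export
simulateSession <- function(spec, cardiacGain = 1, drift = TRUE,
                            ecgNoiseSd = 0.02) {
  stopifnot(is(spec, "ConditionSpec"))
  validObject(spec)
  beats <- makeBeatTimes(spec@hrBpm, spec@durationS,
                         seed = deriveSeed(spec@seed, 7L),
                         hrTime = spec@hrTime, jitterCv = spec@rrJitterCv)
  ecg <- simulateEcg(beats, spec@durationS, fs = 512,
                     seed = deriveSeed(spec@seed, 13L),
                     noiseSd = ecgNoiseSd)
  ecg@meta <- c(ecg@meta, list(posture = spec@posture,
                               physicalState = spec@physicalState,
                               speedKmh = spec@speedKmh,
                               subject = spec@subject))
  motion <- simulateMotion(beats, spec, cardiacGain = cardiacGain,
                           drift = drift)
  new("SimulatedSession", motion = motion, ecg = ecg,
      trueBeatTimes = beats, spec = spec)
}

#' The 12 measurement conditions of the emulated protocol
#'
#' Convenience constructor for the full condition grid: 2 physical states x
#' 3 postures (speed 0) plus 6 treadmill speeds (standing; aroused state for
#' the running-range heart rates).
#'
#' @param durationS per-session duration in seconds.
#' @param subject subject id.
#' @param seed base seed; each condition derives its own.
#' @param snrDb cardiac-to-interference SNR in dB.
#' @return list of 12 [ConditionSpec-class] objects.
#' @export
standardConditions <- function(durationS = 180, subject = "s01", seed = 1L,
                               snrDb = 6) {
  specs <- list()
  i <- 0L
  for (state in c("relaxed", "aroused")) for (post in c("sitting",
                                                        "standing",
                                                        "supine")) {
    i <- i + 1L
    specs[[i]] <- conditionSpec(posture = post, physicalState = state,
                                speedKmh = 0, durationS = durationS,
                                snrDb = snrDb, subject = subject,
                                seed = deriveSeed(seed, i))
  }
  for (sp in SPEEDS_KMH) {
    i <- i + 1L
    specs[[i]] <- conditionSpec(posture = "standing",
                                physicalState = "aroused", speedKmh = sp,
                                durationS = durationS, snrDb = snrDb,
                                subject = subject,
                                seed = deriveSeed(seed, i))
  }
  specs
}
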