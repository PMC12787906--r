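# Synthetic ECG-like records with known R-peak ground truth, and band-
# limited EMG-like noise, emulating the sampling conventions of the MIT-BIH
# databases (360 Hz, single channel, physical millivolts, half-hour traces)
# so the whole pipeline is testable without any download.

# Evaluate expr with a private RNG stream; the caller's global random state
# is left untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic ECG record with known R-peak ground truth
#'
#' Places one QRS template (a Gaussian bump of standard deviation
#' `qrsWidthMs / 5`, so the visible complex spans about `qrsWidthMs`) at
#' each cumulative RR position, optionally followed 300 ms later by a small
#' opposite-sign T-wave bump, on top of sinusoidal baseline wander. The
#' returned annotations hold exactly the template center indices with code
#' `"N"`: generated QRS centers and ground truth coincide by construction.
#' No clinical fidelity is claimed; the morphology is just rich enough for
#' a band-pass/derivative detector chain to behave realistically.
#'
#' @param fs sampling frequency in Hz (default 360, as in the MIT-BIH
#'   Arrhythmia Database).
#' @param durationS record length in seconds (default 1800, a half-hour
#'   trace; tests use much shorter records).
#' @param rrIntervals optional explicit RR sequence in seconds; when `NULL`
#'   RR intervals are drawn as `meanRrS` plus Gaussian jitter of SD
#'   `rrJitterSd`, floored at 0.25 s (the physiological refractory bound).
#' @param meanRrS mean RR interval in seconds (default 0.8, i.e. 75 bpm).
#' @param rrJitterSd RR jitter SD in seconds (default 0.04).
#' @param qrsWidthMs visible QRS width in milliseconds (default 80).
#' @param qrsAmplitudeMv R-peak amplitude in mV (default 1).
#' @param tWaveAmplitudeMv T-wave amplitude in mV, opposite sign to the QRS
#'   (default 0.15; 0 disables it).
#' @param baselineAmplitudeMv baseline-wander amplitude in mV (default 0.1).
#' @param baselineFreqHz baseline-wander frequency in Hz (default 0.3,
#'   respiration-like).
#' @param seed integer seed; the generator is deterministic for a fixed
#'   seed and never touches the global random state.
#' @param recordId record name.
#' @return A list with elements `record` ([EcgRecord-class]) and
#'   `annotations` ([BeatAnnotations-class], `beatOnly = TRUE`).
#' @examples
#' syn <- syntheticEcg(durationS = 10, seed = 1)
#' length(syn$annotations)
#' @export
syntheticEcg <- function(fs = 360, durationS = 1800, rrIntervals = NULL,
                         meanRrS = 0.8, rrJitterSd = 0.04, qrsWidthMs = 80,
                         qrsAmplitudeMv = 1, tWaveAmplitudeMv = 0.15,
                         baselineAmplitudeMv = 0.1, baselineFreqHz = 0.3,
                         seed = 1L, recordId = "synthetic") {
  stopifnot(fs > 0, durationS > 0, qrsWidthMs > 0, qrsAmplitudeMv >= 0,
            tWaveAmplitudeMv >= 0, baselineAmplitudeMv >= 0)
  n <- round(durationS * fs)
  rrSupplied <- !is.null(rrIntervals)
  if (!rrSupplied) {
    # deliberately overshoot, then trim to the record duration
    nBeats <- ceiling(durationS / max(meanRrS, 0.25)) + 2L
    rrIntervals <- .with_seed(seed,
      pmax(stats::rnorm(nBeats, meanRrS, rrJitterSd), 0.25))
  }
  if (any(rrIntervals <= 0.2))
    stop("all RR intervals must exceed 0.2 s (physiological refractory)")
  centersS <- cumsum(rrIntervals)
  margin <- 2.5 * qrsWidthMs / 1000  # keep whole templates inside the record
  inRange <- centersS < durationS - margin
  if (!all(inRange)) {
    if (rrSupplied)
      message("syntheticEcg: truncated ", sum(!inRange),
              " beat(s) beyond the record duration")
    centersS <- centersS[inRange]
  }
  centerIdx <- round(centersS * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- baselineAmplitudeMv * sin(2 * pi * baselineFreqHz * t)
  sdS <- (qrsWidthMs / 5) / 1000
  halfSupport <- ceiling(4 * sdS * fs)
  kernT <- (-halfSupport:halfSupport) / fs
  qrsKernel <- qrsAmplitudeMv * exp(-kernT^2 / (2 * sdS^2))
  tSdS <- 3 * sdS  # T wave is broader and lower than the QRS
  tKernel <- -tWaveAmplitudeMv * exp(-kernT^2 / (2 * tSdS^2))
  tOffset <- round(0.3 * fs)
  for (c0 in centerIdx) {
    idx <- c0 + (-halfSupport:halfSupport) + 1L  # 0-based center -> 1-based
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + qrsKernel[ok]
    if (tWaveAmplitudeMv > 0) {
      idxT <- idx + tOffset
      okT <- idxT >= 1L & idxT <= n
      x[idxT[okT]] <- x[idxT[okT]] + tKernel[okT]
    }
  }
  list(
    record = EcgRecord(x, fs = fs, recordId = recordId),
    annotations = BeatAnnotations(centerIdx,
                                  rep("N", length(centerIdx)),
                                  recordId = recordId, beatOnly = TRUE)
  )
}

#' Generate band-limited EMG-like noise
#'
#' White Gaussian noise band-pass filtered to `bandHz` and rescaled so the
#' sample RMS equals `rmsMv` exactly. The default 15-110 Hz band overlaps
#' the detector's passband, so the noise genuinely perturbs the feature
#' signal, as recorded muscle artifact does. Deterministic for a fixed
#' seed; the global random state is never touched.
#'
#' @param fs sampling frequency in Hz.
#' @param durationS duration in seconds.
#' @param bandHz length-2 numeric, passband (low, high) in Hz with
#'   `0 < low < high < fs/2`.
#' @param rmsMv target RMS amplitude in mV (0 yields an all-zero record).
#' @param seed integer seed.
#' @param recordId record name.
#' @return An [EcgRecord-class].
#' @export
syntheticMuscleNoise <- function(fs = 360, durationS = 1800,
                                 bandHz = c(15, 110), rmsMv = 0.2,
                                 seed = 1L, recordId = "ma_synthetic") {
  stopifnot(fs > 0, durationS > 0, length(bandHz) == 2L, rmsMv >= 0,
            bandHz[1] > 0, bandHz[1] < bandHz[2], bandHz[2] < fs / 2)
  n <- round(durationS * fs)
  if (rmsMv == 0)
    return(EcgRecord(numeric(n), fs = fs, recordId = recordId))
  white <- .with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(2, bandHz / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, white))
  x <- x * rmsMv / sqrt(mean(x^2))
  EcgRecord(x, fs = fs, recordId = recordId)
}
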