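# A traced reimplementation of the moving-window-integration (Pan-Tompkins
# style) QRS detector under study.
#
# The preprocessing chain (band-pass -> first difference -> squaring ->
# causal 150 ms moving-window average) is run causally with no group-delay
# compensation: the uncompensated delay of the feature signal, and the
# decision stage's strict local-maximum test on its plateaus, are exactly
# the behaviors whose jitter this package measures. The decision stage
# records, for every candidate (strict local maximum of the mwa signal),
# the four conditions of the acceptance rule, so its operation can be
# inspected sample by sample.

#' Detector configuration
#'
#' All decision-stage constants of the detector, exposed so the trace can
#' be matched against alternative implementations. Defaults follow the
#' classic Pan-Tompkins constants where the studied implementation does not
#' restate them: signal/noise running-peak smoothing 0.125, threshold a
#' quarter of the way from the noise to the signal peak, searchback
#' triggered at 1.66 times the running RR average with a halved threshold,
#' RR averaged over the last 8 intervals. The refractory period is 300 ms
#' (0.3*fs samples), the extended waiting state of the implementation under
#' test, and the moving-average window is 150 ms (54 samples at 360 Hz).
#'
#' @param fs sampling frequency in Hz.
#' @param bandLowHz,bandHighHz passband edges in Hz (defaults 5 and 15).
#' @param filterOrder band-pass Butterworth order (default 1; run causally,
#'   never forward-backward).
#' @param mwaWindowMs moving-window-average length in ms (default 150).
#' @param refractoryMs post-detection blanking in ms (default 300; must be
#'   at least 200, the physiological bound).
#' @param thresholdSignalUpdate,thresholdNoiseUpdate running-peak smoothing
#'   coefficients (defaults 0.125).
#' @param thresholdFraction position of the threshold between the noise and
#'   signal running peaks (default 0.25).
#' @param searchbackRrFactor RR multiple that triggers searchback (default
#'   1.66).
#' @param searchbackThresholdFraction threshold fraction used during
#'   searchback (default 0.5).
#' @param warmupSuppressMs initial interval in ms during which detections
#'   are suppressed while the running peaks settle (default 300).
#' @return A list of class `DetectorConfig`.
#' @export
detectorConfig <- function(fs = 360, bandLowHz = 5, bandHighHz = 15,
                           filterOrder = 1, mwaWindowMs = 150,
                           refractoryMs = 300,
                           thresholdSignalUpdate = 0.125,
                           thresholdNoiseUpdate = 0.125,
                           thresholdFraction = 0.25,
                           searchbackRrFactor = 1.66,
                           searchbackThresholdFraction = 0.5,
                           warmupSuppressMs = 300) {
  stopifnot(fs > 0, bandLowHz > 0, bandLowHz < bandHighHz,
            bandHighHz < fs / 2, mwaWindowMs > 0)
  if (refractoryMs < 200)
    stop("refractoryMs must be >= 200 ms (physiological refractory)")
  structure(list(
    fs = fs, bandLowHz = bandLowHz, bandHighHz = bandHighHz,
    filterOrder = filterOrder, mwaWindowMs = mwaWindowMs,
    refractoryMs = refractoryMs,
    thresholdSignalUpdate = thresholdSignalUpdate,
    thresholdNoiseUpdate = thresholdNoiseUpdate,
    thresholdFraction = thresholdFraction,
    searchbackRrFactor = searchbackRrFactor,
    searchbackThresholdFraction = searchbackThresholdFraction,
    warmupSuppressMs = warmupSuppressMs
  ), class = "DetectorConfig")
}

#' Run the detector preprocessing chain
#'
#' Causal chain: band-pass filter, first difference, element-wise squaring,
#' then a causal arithmetic moving average over
#' `round(mwaWindowMs * fs / 1000)` samples (54 at 360 Hz) with a growing
#' window during warm-up. All stage outputs stay aligned to the input
#' sample axis; no group-delay compensation is applied.
#'
#' @param rec an [EcgRecord-class] with `samplingRate(rec) == cfg$fs`,
#'   longer than one moving-average window.
#' @param cfg a [detectorConfig()].
#' @return A [FeatureSignal-class].
#' @export
preprocessEcg <- function(rec, cfg = detectorConfig()) {
  stopifnot(is(rec, "EcgRecord"))
  if (samplingRate(rec) != cfg$fs)
    stop("record sampling rate (", samplingRate(rec),
         " Hz) does not match the detector configuration (", cfg$fs, " Hz)")
  x <- samples(rec)
  w <- max(1L, round(cfg$mwaWindowMs * cfg$fs / 1000))
  if (length(x) <= w)
    stop("record shorter than one moving-average window (", w, " samples)")
  bf <- signal::butter(cfg$filterOrder,
                       c(cfg$bandLowHz, cfg$bandHighHz) / (cfg$fs / 2),
                       type = "pass")
  bp <- as.numeric(signal::filter(bf, x))
  d <- c(0, diff(bp))
  sq <- d^2
  cs <- cumsum(sq)
  n <- length(sq)
  mwa <- numeric(n)
  head <- seq_len(min(w, n))
  mwa[head] <- cs[head] / head                       # growing warm-up window
  if (n > w)
    mwa[(w + 1L):n] <- (cs[(w + 1L):n] - cs[1L:(n - w)]) / w
  new("FeatureSignal", fs = cfg$fs, bandpassed = bp, differentiated = d,
      squared = sq, mwa = mwa)
}

#' Run the detector decision stage
#'
#' Scans the moving-window-average feature signal. Every strict local
#' maximum (`mwa[i-1] < mwa[i]` and `mwa[i+1] < mwa[i]`; a flat plateau
#' yields no candidate) is a candidate; a candidate becomes a beat label
#' iff it exceeds the adaptive threshold and lies more than `0.3 * fs`
#' samples after the previous beat label. Accepted candidates update the
#' running signal peak, rejected ones the running noise peak, and the
#' threshold sits `thresholdFraction` of the way between them. When the
#' elapsed interval since the last beat exceeds
#' `searchbackRrFactor` times the running average of the last 8 RR
#' intervals, the candidates since that beat are re-scanned at
#' `searchbackThresholdFraction` of the threshold and the largest one is
#' emitted retroactively (flagged `searchback` in the trace). Candidates in
#' the first `warmupSuppressMs` are suppressed via the refractory
#' condition. The running peaks are seeded from the maximum and mean of the
#' feature signal over the first two seconds, so all thresholds are
#' data-driven and the detections are invariant under positive rescaling of
#' the input.
#'
#' @param feat a [FeatureSignal-class] produced by [preprocessEcg()] with
#'   the same configuration.
#' @param cfg a [detectorConfig()].
#' @return A [DetectionResult-class]; an empty detection list is a valid
#'   result.
#' @export
detectBeats <- function(feat, cfg = detectorConfig()) {
  stopifnot(is(feat, "FeatureSignal"))
  m <- feat@mwa
  n <- length(m)
  fs <- cfg$fs
  refr <- 0.3 * fs                      # strict ">" comparison, in samples
  warmup <- round(cfg$warmupSuppressMs * fs / 1000)
  tsu <- cfg$thresholdSignalUpdate
  tnu <- cfg$thresholdNoiseUpdate
  tf <- cfg$thresholdFraction

  j <- 2:(n - 1)                                      # 1-based interior
  isCand <- m[j - 1L] < m[j] & m[j + 1L] < m[j]
  cand <- (j[isCand]) - 1L                            # 0-based indices
  nc <- length(cand)
  candVal <- m[cand + 1L]

  seedIdx <- seq_len(min(n, max(2L, round(2 * fs))))
  spk <- max(m[seedIdx])
  npk <- mean(m[seedIdx])
  threshold <- npk + tf * (spk - npk)
  thInit <- threshold

  lastBeat <- warmup - refr    # candidates before warm-up fail refractory
  haveBeat <- FALSE
  rr <- numeric(0)             # last 8 accepted RR intervals
  lastPtr <- 0L                # candidate pointer of the last accepted beat

  above <- logical(nc); outside <- logical(nc); accepted <- logical(nc)
  sback <- logical(nc); thAt <- numeric(nc); thAfter <- numeric(nc)
  beats <- integer(0)

  for (k in seq_len(nc)) {
    i <- cand[k]
    # searchback: abnormally long interval since the last beat
    if (haveBeat && length(rr) >= 1L &&
        (i - lastBeat) > cfg$searchbackRrFactor * mean(rr)) {
      sel <- if (lastPtr + 1L <= k - 1L) (lastPtr + 1L):(k - 1L)
             else integer(0)
      sel <- sel[!accepted[sel] & cand[sel] > lastBeat + refr &
                 candVal[sel] > cfg$searchbackThresholdFraction * threshold]
      if (length(sel)) {
        kk <- sel[which.max(candVal[sel])]
        accepted[kk] <- TRUE
        sback[kk] <- TRUE
        rr <- c(rr, cand[kk] - lastBeat)
        if (length(rr) > 8L) rr <- rr[(length(rr) - 7L):length(rr)]
        lastBeat <- cand[kk]
        lastPtr <- kk
        beats <- c(beats, cand[kk])
        spk <- 0.25 * candVal[kk] + 0.75 * spk   # classic searchback update
        threshold <- npk + tf * (spk - npk)
      }
    }
    thAt[k] <- threshold
    above[k] <- m[i + 1L] > threshold
    outside[k] <- (i - lastBeat) > refr
    if (above[k] && outside[k]) {
      accepted[k] <- TRUE
      if (haveBeat) {
        rr <- c(rr, i - lastBeat)
        if (length(rr) > 8L) rr <- rr[(length(rr) - 7L):length(rr)]
      }
      lastBeat <- i
      haveBeat <- TRUE
      lastPtr <- k
      beats <- c(beats, i)
      spk <- tsu * candVal[k] + (1 - tsu) * spk
    } else {
      npk <- tnu * candVal[k] + (1 - tnu) * npk
    }
    threshold <- npk + tf * (spk - npk)
    thAfter[k] <- threshold
  }

  # per-sample threshold: value in force for a decision at that sample
  thVec <- rep(thInit, n)
  if (nc) {
    bounds <- c(cand + 2L, n + 1L)  # sample after each candidate (1-based)
    for (k in seq_len(nc)) {
      from <- bounds[k]; to <- bounds[k + 1L] - 1L
      if (from <= to) thVec[from:to] <- thAfter[k]
    }
  }

  trace <- data.frame(
    sample_index = cand,
    rising = rep(TRUE, nc), falling = rep(TRUE, nc),
    above_threshold = above, outside_refractory = outside,
    accepted = accepted, threshold = thAt, searchback = sback
  )
  new("DetectionResult", beatLabels = sort(beats), trace = trace,
      thresholdI1 = thVec, mwa = m, config = unclass(cfg))
}

#' Detect beats in an ECG record
#'
#' Convenience wrapper composing [preprocessEcg()] and [detectBeats()].
#'
#' @inheritParams preprocessEcg
#' @return A [DetectionResult-class].
#' @examples
#' syn <- syntheticEcg(durationS = 20, seed = 7)
#' det <- detectEcg(syn$record)
#' length(beatLabels(det))
#' @export
detectEcg <- function(rec, cfg = detectorConfig(fs = samplingRate(rec))) {
  detectBeats(preprocessEcg(rec, cfg), cfg)
}

#' Extract a window of the decision-stage trace
#'
#' Returns the candidate rows (strict local maxima of the feature signal)
#' whose sample index lies in `[start, end]`, plus boundary rows for the
#' `start` and `end` samples themselves with their conditions evaluated in
#' place, in the truth-table layout of the decision stage.
#'
#' @param x a [DetectionResult-class].
#' @param start,end 0-based sample indices, `start < end`, within the
#'   record.
#' @return A data.frame with the trace columns.
#' @name traceWindow
#' @export
setMethod("traceWindow", "DetectionResult", function(x, start, end) {
  n <- length(x@mwa)
  if (start >= end) stop("start must be less than end")
  if (start < 0 || end > n - 1L)
    stop("window [", start, ", ", end, "] out of range [0, ", n - 1L, "]")
  rows <- x@trace[x@trace$sample_index >= start &
                  x@trace$sample_index <= end, , drop = FALSE]
  boundary <- function(s) {
    j <- s + 1L  # 1-based
    rising <- j > 1L && x@mwa[j - 1L] < x@mwa[j]
    falling <- j < n && x@mwa[j + 1L] < x@mwa[j]
    prevBeats <- x@beatLabels[x@beatLabels < s]
    refr <- 0.3 * x@config$fs
    warmup <- round(x@config$warmupSuppressMs * x@config$fs / 1000)
    lastBeat <- if (length(prevBeats)) max(prevBeats) else warmup - refr
    data.frame(sample_index = s, rising = rising, falling = falling,
               above_threshold = x@mwa[j] > x@thresholdI1[j],
               outside_refractory = (s - lastBeat) > refr,
               accepted = s %in% x@beatLabels,
               threshold = x@thresholdI1[j],
               searchback = s %in% x@trace$sample_index[x@trace$searchback])
  }
  for (s in c(start, end))
    if (!s %in% rows$sample_index) rows <- rbind(rows, boundary(s))
  rows <- rows[order(rows$sample_index), , drop = FALSE]
  rownames(rows) <- NULL
  rows
})
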