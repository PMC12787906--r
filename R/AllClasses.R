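#' @import methods
NULL

#' Single-channel ECG record
#'
#' One uniformly sampled ECG channel in physical units (millivolts).
#' Sample indices are 0-based from record start throughout the package, so
#' annotation sample numbers from MIT-format files can be used verbatim.
#'
#' @slot recordId character(1), record name.
#' @slot fs numeric(1), sampling frequency in Hz.
#' @slot samples numeric vector of amplitudes in mV.
#' @slot channelIndex integer(1), 1-based channel of the source record the
#'   samples were taken from.
#'
#' @exportClass EcgRecord
setClass("EcgRecord",
  representation(
    recordId = "character",
    fs = "numeric",
    samples = "numeric",
    channelIndex = "integer"
  ),
  prototype(recordId = "record", fs = 360, samples = numeric(0),
            channelIndex = 1L)
)

setValidity("EcgRecord", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "all amplitudes must be finite")
  if (length(object@channelIndex) != 1L || object@channelIndex < 1L)
    msg <- c(msg, "channelIndex must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Reference beat annotations
#'
#' Ordered beat labels as 0-based sample indices with single-character
#' annotation codes (PhysioBank mnemonics: 'N', 'V', '+', '~', ...).
#'
#' @slot recordId character(1).
#' @slot sampleIndex integer vector, strictly increasing, 0-based.
#' @slot code character vector of single-character annotation symbols.
#' @slot beatOnly logical(1), TRUE once non-beat codes have been filtered
#'   out with [filterBeatAnnotations()].
#'
#' @exportClass BeatAnnotations
setClass("BeatAnnotations",
  representation(
    recordId = "character",
    sampleIndex = "integer",
    code = "character",
    beatOnly = "logical"
  ),
  prototype(recordId = "record", sampleIndex = integer(0),
            code = character(0), beatOnly = FALSE)
)

setValidity("BeatAnnotations", function(object) {
  msg <- character(0)
  if (length(object@sampleIndex) != length(object@code))
    msg <- c(msg, "sampleIndex and code must have equal length")
  if (length(object@sampleIndex) > 1L &&
      any(diff(object@sampleIndex) <= 0L))
    msg <- c(msg, "sampleIndex must be strictly increasing")
  if (length(object@sampleIndex) && any(object@sampleIndex < 0L))
    msg <- c(msg, "sampleIndex must be non-negative")
  if (length(object@code) && any(nchar(object@code) != 1L))
    msg <- c(msg, "codes must be single characters")
  if (length(object@beatOnly) != 1L)
    msg <- c(msg, "beatOnly must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Detector feature signal
#'
#' The intermediate stages of the detector preprocessing chain, all on the
#' same sample axis as the input record (causal filters, no group-delay
#' compensation): band-passed signal, its first difference, the square, and
#' the causal moving-window average (mwa) that the decision stage scans.
#'
#' @slot fs numeric(1), sampling frequency in Hz.
#' @slot bandpassed numeric vector.
#' @slot differentiated numeric vector.
#' @slot squared numeric vector.
#' @slot mwa numeric vector, non-negative.
#'
#' @exportClass FeatureSignal
setClass("FeatureSignal",
  representation(
    fs = "numeric",
    bandpassed = "numeric",
    differentiated = "numeric",
    squared = "numeric",
    mwa = "numeric"
  )
)

setValidity("FeatureSignal", function(object) {
  msg <- character(0)
  n <- length(object@mwa)
  if (length(object@bandpassed) != n || length(object@differentiated) != n ||
      length(object@squared) != n)
    msg <- c(msg, "all stage outputs must share one sample axis")
  if (n && min(object@mwa) < -1e-12)
    msg <- c(msg, "mwa must be non-negative (it averages a squared signal)")
  if (length(msg)) msg else TRUE
})

#' Detection result with decision-stage trace
#'
#' Beat labels emitted by the detector plus a complete per-candidate trace
#' of the decision stage: for every strict local maximum of the mwa signal,
#' the four boolean conditions (rising slope, falling slope, above the
#' adaptive threshold, outside the refractory period) and whether the
#' candidate was accepted as a beat.
#'
#' @slot beatLabels integer vector of 0-based sample indices, strictly
#'   increasing, consecutive labels more than 0.3*fs samples apart.
#' @slot trace data.frame, one row per candidate with columns
#'   `sample_index`, `rising`, `falling`, `above_threshold`,
#'   `outside_refractory`, `accepted`, `threshold`, `searchback`.
#' @slot thresholdI1 numeric vector, the adaptive threshold at every sample
#'   (piecewise constant between candidates).
#' @slot mwa numeric vector, the feature signal the decisions were made on.
#' @slot config list, the detector configuration used.
#'
#' @exportClass DetectionResult
setClass("DetectionResult",
  representation(
    beatLabels = "integer",
    trace = "data.frame",
    thresholdI1 = "numeric",
    mwa = "numeric",
    config = "list"
  )
)

setValidity("DetectionResult", function(object) {
  msg <- character(0)
  bl <- object@beatLabels
  if (length(bl) > 1L && any(diff(bl) <= 0L))
    msg <- c(msg, "beatLabels must be strictly increasing")
  fs <- object@config$fs
  if (!is.null(fs) && length(bl) > 1L && any(diff(bl) <= 0.3 * fs))
    msg <- c(msg, "consecutive beatLabels must differ by more than 0.3*fs")
  if (length(object@thresholdI1) != length(object@mwa))
    msg <- c(msg, "thresholdI1 and mwa must share one sample axis")
  if (length(msg)) msg else TRUE
})

#' Tolerance-parameterized beat pairing
#'
#' One-to-one matching of reference and detected beats under a detection
#' time tolerance (DTT), with signed jitter per pair and the unmatched
#' detections (false positives) and references (false negatives).
#'
#' @slot dttSamples integer(1), tolerance in samples (inclusive).
#' @slot pairs data.frame with columns `ref`, `det`, `jitter`
#'   (jitter = det - ref, signed, |jitter| <= dttSamples).
#' @slot fpIndices integer vector, unmatched detection sample indices.
#' @slot fnIndices integer vector, unmatched reference sample indices.
#'
#' @exportClass DttPairing
setClass("DttPairing",
  representation(
    dttSamples = "integer",
    pairs = "data.frame",
    fpIndices = "integer",
    fnIndices = "integer"
  )
)

setValidity("DttPairing", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (!all(c("ref", "det", "jitter") %in% names(p)))
    msg <- c(msg, "pairs must have columns ref, det, jitter")
  else {
    if (nrow(p) && any(abs(p$jitter) > object@dttSamples))
      msg <- c(msg, "every pair must satisfy |jitter| <= dttSamples")
    if (nrow(p) && !identical(p$jitter, p$det - p$ref))
      msg <- c(msg, "jitter must equal det - ref")
    if (anyDuplicated(p$ref) || anyDuplicated(p$det))
      msg <- c(msg, "each reference and detection appears in at most one pair")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a DTT-by-SNR benchmark sweep
#'
#' Per-record and pooled confusion counts and detection statistics over a
#' grid of detection time tolerances and added-noise SNR levels. Pooled
#' statistics are always recomputed from summed TP/FN/FP counts, never
#' averaged from per-record percentages.
#'
#' @slot perRecord data.frame, one row per (record, dtt, snr) cell.
#' @slot pooled data.frame, one row per (dtt, snr) cell with summed counts.
#' @slot dttGrid integer vector of tolerances in samples.
#' @slot snrDb numeric vector of target SNR levels in dB (NA = no noise).
#' @slot detectorConfig list.
#'
#' @exportClass SweepResult
setClass("SweepResult",
  representation(
    perRecord = "data.frame",
    pooled = "data.frame",
    dttGrid = "integer",
    snrDb = "numeric",
    detectorConfig = "list"
  )
)
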