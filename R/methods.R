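# Accessors, constructors and show methods for the S4 containers.

#' Construct an EcgRecord
#'
#' @param samples numeric vector of amplitudes in millivolts.
#' @param fs sampling frequency in Hz.
#' @param recordId record name.
#' @param channelIndex 1-based channel of the source record.
#' @return An [EcgRecord-class] object.
#' @examples
#' rec <- EcgRecord(sin(2 * pi * 1 * (0:719) / 360), fs = 360)
#' nSamples(rec)
#' @export
EcgRecord <- function(samples, fs, recordId = "record", channelIndex = 1L) {
  new("EcgRecord", recordId = as.character(recordId), fs = as.numeric(fs),
      samples = as.numeric(samples), channelIndex = as.integer(channelIndex))
}

#' Construct BeatAnnotations
#'
#' @param sampleIndex integer vector of 0-based sample indices, strictly
#'   increasing.
#' @param code character vector of single-character annotation symbols.
#' @param recordId record name.
#' @param beatOnly logical, whether non-beat codes have been filtered.
#' @return A [BeatAnnotations-class] object.
#' @export
BeatAnnotations <- function(sampleIndex, code, recordId = "record",
                            beatOnly = FALSE) {
  new("BeatAnnotations", recordId = as.character(recordId),
      sampleIndex = as.integer(sampleIndex), code = as.character(code),
      beatOnly = isTRUE(beatOnly))
}

#' Accessors for EcgRecord
#'
#' `recordId()`, `samplingRate()`, `samples()` and `nSamples()` extract the
#' record name, sampling frequency (Hz), amplitude vector (mV) and number of
#' samples.
#'
#' @param x an [EcgRecord-class] (or, for `recordId`, a
#'   [BeatAnnotations-class]).
#' @name EcgRecord-accessors
#' @aliases recordId samplingRate samples nSamples
NULL

#' @rdname EcgRecord-accessors
#' @export
setMethod("recordId", "EcgRecord", function(x) x@recordId)

#' @rdname EcgRecord-accessors
#' @export
setMethod("recordId", "BeatAnnotations", function(x) x@recordId)

#' @rdname EcgRecord-accessors
#' @export
setMethod("samplingRate", "EcgRecord", function(x) x@fs)

#' @rdname EcgRecord-accessors
#' @export
setMethod("samplingRate", "FeatureSignal", function(x) x@fs)

#' @rdname EcgRecord-accessors
#' @export
setMethod("samples", "EcgRecord", function(x) x@samples)

#' @rdname EcgRecord-accessors
#' @export
setMethod("nSamples", "EcgRecord", function(x) length(x@samples))

#' Accessors for BeatAnnotations
#'
#' `sampleIndex()` returns the 0-based annotation sample indices,
#' `annCode()` the single-character codes, `isBeatOnly()` whether non-beat
#' codes have been filtered out.
#'
#' @param x a [BeatAnnotations-class].
#' @name BeatAnnotations-accessors
#' @aliases sampleIndex annCode isBeatOnly
NULL

#' @rdname BeatAnnotations-accessors
#' @export
setMethod("sampleIndex", "BeatAnnotations", function(x) x@sampleIndex)

#' @rdname BeatAnnotations-accessors
#' @export
setMethod("annCode", "BeatAnnotations", function(x) x@code)

#' @rdname BeatAnnotations-accessors
#' @export
setMethod("isBeatOnly", "BeatAnnotations", function(x) x@beatOnly)

#' @export
setMethod("length", "BeatAnnotations", function(x) length(x@sampleIndex))

#' Accessors for DetectionResult
#'
#' `beatLabels()` returns the emitted beat labels (0-based sample indices),
#' `decisionTrace()` the per-candidate condition table, `mwa()` the feature
#' signal and `thresholdI1()` the adaptive threshold at every sample.
#'
#' @param x a [DetectionResult-class] (or [FeatureSignal-class] for `mwa`).
#' @name DetectionResult-accessors
#' @aliases beatLabels decisionTrace mwa thresholdI1
NULL

#' @rdname DetectionResult-accessors
#' @export
setMethod("beatLabels", "DetectionResult", function(x) x@beatLabels)

#' @rdname DetectionResult-accessors
#' @export
setMethod("decisionTrace", "DetectionResult", function(x) x@trace)

#' @rdname DetectionResult-accessors
#' @export
setMethod("mwa", "FeatureSignal", function(x) x@mwa)

#' @rdname DetectionResult-accessors
#' @export
setMethod("mwa", "DetectionResult", function(x) x@mwa)

#' @rdname DetectionResult-accessors
#' @export
setMethod("thresholdI1", "DetectionResult", function(x) x@thresholdI1)

#' Accessors for DttPairing
#'
#' `beatPairs()` returns the matched (ref, det, jitter) table, `fpIndices()`
#' the unmatched detections, `fnIndices()` the unmatched references and
#' `dttSamples()` the tolerance used.
#'
#' @param x a [DttPairing-class].
#' @name DttPairing-accessors
#' @aliases beatPairs fpIndices fnIndices dttSamples
NULL

#' @rdname DttPairing-accessors
#' @export
setMethod("beatPairs", "DttPairing", function(x) x@pairs)

#' @rdname DttPairing-accessors
#' @export
setMethod("fpIndices", "DttPairing", function(x) x@fpIndices)

#' @rdname DttPairing-accessors
#' @export
setMethod("fnIndices", "DttPairing", function(x) x@fnIndices)

#' @rdname DttPairing-accessors
#' @export
setMethod("dttSamples", "DttPairing", function(x) x@dttSamples)

#' Accessors for SweepResult
#'
#' `pooledMetrics()` returns the pooled (summed-counts) statistics per
#' (DTT, SNR) cell; `perRecordMetrics()` the per-record table.
#'
#' @param x a [SweepResult-class].
#' @name SweepResult-accessors
#' @aliases pooledMetrics perRecordMetrics
NULL

#' @rdname SweepResult-accessors
#' @export
setMethod("pooledMetrics", "SweepResult", function(x) x@pooled)

#' @rdname SweepResult-accessors
#' @export
setMethod("perRecordMetrics", "SweepResult", function(x) x@perRecord)

setMethod("show", "EcgRecord", function(object) {
  cat("EcgRecord '", object@recordId, "': ", length(object@samples),
      " samples @ ", object@fs, " Hz (",
      sprintf("%.1f", length(object@samples) / object@fs), " s), channel ",
      object@channelIndex, "\n", sep = "")
  if (length(object@samples))
    cat("  amplitude range [", sprintf("%.3f", min(object@samples)), ", ",
        sprintf("%.3f", max(object@samples)), "] mV\n", sep = "")
})

setMethod("show", "BeatAnnotations", function(object) {
  cat("BeatAnnotations '", object@recordId, "': ",
      length(object@sampleIndex), " entries",
      if (object@beatOnly) " (beat codes only)" else "", "\n", sep = "")
  if (length(object@code)) {
    tab <- sort(table(object@code), decreasing = TRUE)
    cat("  codes:", paste0(names(tab), ":", tab, collapse = " "), "\n")
  }
})

setMethod("show", "FeatureSignal", function(object) {
  cat("FeatureSignal: ", length(object@mwa), " samples @ ", object@fs,
      " Hz; stages: bandpassed, differentiated, squared, mwa\n", sep = "")
})

setMethod("show", "DetectionResult", function(object) {
  cat("DetectionResult: ", length(object@beatLabels), " beat labels, ",
      nrow(object@trace), " candidates traced\n", sep = "")
  if (nrow(object@trace)) {
    acc <- sum(object@trace$accepted)
    sb <- sum(object@trace$searchback)
    cat("  accepted: ", acc, " (", sb, " via searchback), rejected: ",
        nrow(object@trace) - acc, "\n", sep = "")
  }
})

setMethod("show", "DttPairing", function(object) {
  cat("DttPairing (DTT = ", object@dttSamples, " samples): TP = ",
      nrow(object@pairs), ", FP = ", length(object@fpIndices), ", FN = ",
      length(object@fnIndices), "\n", sep = "")
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult: ", length(unique(object@perRecord$record)),
      " record(s) x ", length(object@dttGrid), " DTT x ",
      length(object@snrDb), " SNR cells\n", sep = "")
})
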