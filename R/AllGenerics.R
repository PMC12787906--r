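#' @rdname EcgRecord-accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname EcgRecord-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EcgRecord-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname EcgRecord-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname BeatAnnotations-accessors
#' @export
setGeneric("sampleIndex", function(x) standardGeneric("sampleIndex"))

#' @rdname BeatAnnotations-accessors
#' @export
setGeneric("annCode", function(x) standardGeneric("annCode"))

#' @rdname BeatAnnotations-accessors
#' @export
setGeneric("isBeatOnly", function(x) standardGeneric("isBeatOnly"))

#' @rdname DetectionResult-accessors
#' @export
setGeneric("beatLabels", function(x) standardGeneric("beatLabels"))

#' @rdname DetectionResult-accessors
#' @export
setGeneric("decisionTrace", function(x) standardGeneric("decisionTrace"))

#' @rdname DetectionResult-accessors
#' @export
setGeneric("mwa", function(x) standardGeneric("mwa"))

#' @rdname DetectionResult-accessors
#' @export
setGeneric("thresholdI1", function(x) standardGeneric("thresholdI1"))

#' @rdname traceWindow
#' @export
setGeneric("traceWindow",
           function(x, start, end) standardGeneric("traceWindow"))

#' @rdname DttPairing-accessors
#' @export
setGeneric("beatPairs", function(x) standardGeneric("beatPairs"))

#' @rdname DttPairing-accessors
#' @export
setGeneric("fpIndices", function(x) standardGeneric("fpIndices"))

#' @rdname DttPairing-accessors
#' @export
setGeneric("fnIndices", function(x) standardGeneric("fnIndices"))

#' @rdname DttPairing-accessors
#' @export
setGeneric("dttSamples", function(x) standardGeneric("dttSamples"))

#' @rdname detectionMetrics
#' @export
setGeneric("detectionMetrics", function(x, ...)
  standardGeneric("detectionMetrics"))

#' @rdname SweepResult-accessors
#' @export
setGeneric("pooledMetrics", function(x) standardGeneric("pooledMetrics"))

#' @rdname SweepResult-accessors
#' @export
setGeneric("perRecordMetrics", function(x)
  standardGeneric("perRecordMetrics"))
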