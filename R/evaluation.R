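# Pairing of reference and detected beats, and detection statistics.
#
# Two pairing schemes are provided: tolerance-parameterized one-to-one
# matching (a pair must lie within +/- DTT samples, comparison inclusive)
# and tolerance-free mutual-nearest-neighbor proximity pairing for the
# jitter-discounted JF benchmark.

.as_ref_vector <- function(refs) {
  if (is(refs, "BeatAnnotations")) as.numeric(sampleIndex(refs))
  else as.numeric(refs)
}

#' Pair reference and detected beats under a detection time tolerance
#'
#' Builds a one-to-one matching between sorted reference and detection
#' sample indices: candidate pairs within `dttSamples` (inclusive,
#' `|det - ref| <= DTT`) are accepted greedily by ascending absolute
#' difference, ties broken toward the earlier reference and then the
#' earlier detection. The greedy matching is deterministic and equals the
#' maximum-cardinality matching whenever consecutive beats are separated by
#' more than twice the tolerance, which holds for all tolerances studied
#' here against a 300 ms refractory.
#'
#' @param refs a [BeatAnnotations-class] or sorted numeric vector of
#'   reference sample indices.
#' @param dets sorted numeric vector of detected sample indices (or a
#'   [DetectionResult-class]).
#' @param dttSamples tolerance in samples, `>= 0`.
#' @return A [DttPairing-class].
#' @export
pairWithTolerance <- function(refs, dets, dttSamples) {
  r <- .as_ref_vector(refs)
  if (is(dets, "DetectionResult")) dets <- beatLabels(dets)
  d <- as.numeric(dets)
  if (is.unsorted(r, strictly = FALSE) || is.unsorted(d, strictly = FALSE))
    stop("reference and detection sequences must be sorted")
  dttSamples <- as.integer(dttSamples)
  stopifnot(dttSamples >= 0L)
  # enumerate candidate pairs within the tolerance
  cr <- integer(0); cd <- integer(0)
  if (length(r) && length(d)) {
    lo <- findInterval(r - dttSamples - 0.5, d) + 1L
    hi <- findInterval(r + dttSamples + 0.5, d)
    nPer <- pmax(hi - lo + 1L, 0L)
    cr <- rep.int(seq_along(r), nPer)
    cd <- unlist(lapply(seq_along(r), function(i)
      if (nPer[i] > 0L) lo[i]:hi[i] else integer(0)), use.names = FALSE)
  }
  usedR <- logical(length(r)); usedD <- logical(length(d))
  pr <- integer(0); pd <- integer(0)
  if (length(cr)) {
    delta <- abs(d[cd] - r[cr])
    for (k in order(delta, cr, cd)) {
      i <- cr[k]; jd <- cd[k]
      if (!usedR[i] && !usedD[jd]) {
        usedR[i] <- TRUE; usedD[jd] <- TRUE
        pr <- c(pr, i); pd <- c(pd, jd)
      }
    }
  }
  ordRef <- order(r[pr])
  pairs <- data.frame(ref = r[pr][ordRef], det = d[pd][ordRef],
                      jitter = (d[pd] - r[pr])[ordRef])
  new("DttPairing", dttSamples = dttSamples, pairs = pairs,
      fpIndices = as.integer(d[!usedD]), fnIndices = as.integer(r[!usedR]))
}

.metric_row <- function(tp, fn, fp) {
  if (tp + fn == 0)
    stop("TP + FN = 0: Se and DER are undefined for an empty reference set")
  se <- 100 * tp / (tp + fn)
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(ppv) && (ppv + se) > 0) 2 * ppv * se / (ppv + se)
        else NA_real_
  data.frame(TB = tp + fn, TP = tp, FN = fn, FP = fp,
             DER = 100 * (fp + fn) / (tp + fn), Se = se, PPV = ppv, F1 = f1)
}

#' Detection statistics from confusion counts or a pairing
#'
#' Computes TB, DER, Se, PPV and F1 (as percentages, full precision;
#' rounding is for display only): `DER = (FP + FN) / (TP + FN)`,
#' `Se = TP / (TP + FN)`, `PPV = TP / (TP + FP)`,
#' `F1 = 2 * PPV * Se / (PPV + Se)`. DER may exceed 100%. An empty
#' reference set (`TP + FN = 0`) is an error, not a number.
#'
#' @param x a [DttPairing-class], or the TP count when calling the
#'   count-based form `detectionMetrics(tp, fn = , fp = )`.
#' @param fn,fp false-negative and false-positive counts (count-based form
#'   only).
#' @param ... unused.
#' @return A one-row data.frame with columns `TB`, `TP`, `FN`, `FP`,
#'   `DER`, `Se`, `PPV`, `F1`.
#' @examples
#' detectionMetrics(105118, fn = 4376, fp = 4469)  # DER 8.08, Se 96.00
#' @name detectionMetrics
NULL

#' @rdname detectionMetrics
#' @export
setMethod("detectionMetrics", "DttPairing", function(x, ...) {
  .metric_row(nrow(x@pairs), length(x@fnIndices), length(x@fpIndices))
})

#' @rdname detectionMetrics
#' @export
setMethod("detectionMetrics", "numeric", function(x, fn, fp, ...) {
  .metric_row(x, fn, fp)
})

#' Tolerance-free proximity pairing
#'
#' Pairs references and detections by mutual nearest neighbor with no
#' tolerance cap: a reference and a detection are paired iff each is the
#' nearest label of the other (ties broken toward the earlier label).
#' Unpaired detections count as FP, unpaired references as FN.
#'
#' @inheritParams pairWithTolerance
#' @return A list with `tpJf`, `fpJf`, `fnJf` counts and `pairs`, a
#'   data.frame with columns `ref`, `det`, `jitter`.
#' @export
pairByProximity <- function(refs, dets) {
  r <- .as_ref_vector(refs)
  if (is(dets, "DetectionResult")) dets <- beatLabels(dets)
  d <- as.numeric(dets)
  if (is.unsorted(r) || is.unsorted(d))
    stop("reference and detection sequences must be sorted")
  nearest <- function(from, to) {
    # index in `to` of the nearest value for each element of `from`;
    # ties go to the earlier label
    if (!length(to)) return(rep(NA_integer_, length(from)))
    pos <- findInterval(from, to)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(to))
    dLo <- abs(from - to[lo])
    dHi <- abs(from - to[hi])
    ifelse(dLo <= dHi, lo, hi)
  }
  if (!length(r) || !length(d)) {
    return(list(tpJf = 0L, fpJf = length(d), fnJf = length(r),
                pairs = data.frame(ref = numeric(0), det = numeric(0),
                                   jitter = numeric(0))))
  }
  nd <- nearest(r, d)   # nearest detection for each reference
  nr <- nearest(d, r)   # nearest reference for each detection
  mutual <- which(nr[nd] == seq_along(r))
  pairs <- data.frame(ref = r[mutual], det = d[nd[mutual]],
                      jitter = d[nd[mutual]] - r[mutual])
  list(tpJf = length(mutual),
       fpJf = length(d) - length(mutual),
       fnJf = length(r) - length(mutual),
       pairs = pairs)
}

#' Jitter-to-performance discount
#'
#' Maps the average absolute temporal jitter to a multiplicative
#' performance factor `1 / (1 + jitter / 12 ms)`: 0 ms scores 1, 12 ms
#' scores 0.5, and the factor decreases strictly towards 0.
#'
#' @param meanAbsJitterMs mean absolute jitter in milliseconds, `>= 0`.
#' @return A fraction in `(0, 1]`.
#' @examples
#' jitterToScore(12)  # 0.5
#' @export
jitterToScore <- function(meanAbsJitterMs) {
  if (any(meanAbsJitterMs < 0))
    stop("mean absolute jitter must be non-negative")
  1 / (1 + meanAbsJitterMs / 12)
}

#' The jitter-discounted JF benchmark
#'
#' Composes [pairByProximity()], the mean absolute jitter over the matched
#' pairs (converted to ms via `fs`), the F1 score on the proximity counts,
#' and the jitter discount of [jitterToScore()]:
#' `JF = F1_JF * f(mean |jitter|)`, expressed in percent.
#'
#' @inheritParams pairWithTolerance
#' @param fs sampling frequency in Hz, used to convert jitter from samples
#'   to milliseconds.
#' @return A list with `tpJf`, `fpJf`, `fnJf`, `meanAbsJitterMs`,
#'   `jitterScore`, `f1Jf` (percent), `jf` (percent) and `pairs`.
#' @export
jfScore <- function(refs, dets, fs) {
  stopifnot(fs > 0)
  prox <- pairByProximity(refs, dets)
  if (prox$tpJf == 0)
    stop("no proximity-matched pairs: the average jitter is undefined")
  meanAbsJitterMs <- mean(abs(prox$pairs$jitter)) * 1000 / fs
  fj <- jitterToScore(meanAbsJitterMs)
  f1 <- .metric_row(prox$tpJf, prox$fnJf, prox$fpJf)$F1
  c(prox[c("tpJf", "fpJf", "fnJf")],
    list(meanAbsJitterMs = meanAbsJitterMs, jitterScore = fj,
         f1Jf = f1, jf = f1 * fj, pairs = prox$pairs))
}

#' Histogram of signed detection jitter
#'
#' Counts the signed jitters (det - ref, in samples) over the pairs of one
#' or more pairings into fixed-width bins whose centers are aligned at 0.
#'
#' @param pairings a [DttPairing-class] or a list of them.
#' @param binWidthSamples bin width in samples (default 1).
#' @return A data.frame with columns `center` (bin center in samples) and
#'   `count`; empty bins inside the observed range are included.
#' @export
jitterHistogram <- function(pairings, binWidthSamples = 1L) {
  if (is(pairings, "DttPairing")) pairings <- list(pairings)
  jit <- unlist(lapply(pairings, function(p) beatPairs(p)$jitter))
  w <- binWidthSamples
  if (!length(jit))
    return(data.frame(center = numeric(0), count = integer(0)))
  bin <- round(jit / w)
  rng <- seq(min(bin), max(bin))
  counts <- tabulate(bin - min(bin) + 1L, nbins = length(rng))
  data.frame(center = rng * w, count = counts)
}

#' Convert a tolerance in samples to milliseconds
#'
#' @param dttSamples tolerance in samples.
#' @param fs sampling frequency in Hz.
#' @return `dttSamples * 1000 / fs`, full precision (display rounds to two
#'   decimals).
#' @examples
#' dttToMs(35, 360)  # 97.22...
#' @export
dttToMs <- function(dttSamples, fs) {
  stopifnot(fs > 0)
  dttSamples * 1000 / fs
}
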