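# Relative-SNR computation and controlled noise mixing.
#
# The SNR here is *relative*: it is computed from the raw record including
# its intrinsic noise (20*log10 of the RMS ratio of the record and the
# added, scaled noise trace), with no attempt to estimate clean-signal
# power. RMS is taken over the full record. "No noise added" is a sentinel
# (targetSnrDb = NA), not an infinite dB value.

#' Root-mean-square amplitude
#'
#' @param x numeric vector (non-empty, finite), amplitudes in mV, or an
#'   [EcgRecord-class].
#' @return sqrt of the mean of squares, in mV.
#' @examples
#' rmsAmplitude(c(3, 4, 0, 0))  # 2.5
#' @export
rmsAmplitude <- function(x) {
  if (is(x, "EcgRecord")) x <- samples(x)
  if (!length(x)) stop("cannot compute the RMS of an empty sequence")
  if (anyNA(x) || any(!is.finite(x))) stop("RMS input must be finite")
  sqrt(mean(x^2))
}

#' Relative signal-to-noise ratio in dB
#'
#' `20 * log10(RMSs / RMSn)` where RMSs is the RMS of the raw record
#' (intrinsic noise included) and RMSn the RMS of the noise trace. A
#' zero-RMS noise trace is an error: an infinite SNR is represented by the
#' "no noise added" sentinel (`NA`), never by a number.
#'
#' @param sig,noise [EcgRecord-class] objects or numeric vectors.
#' @return SNR in dB.
#' @export
relativeSnr <- function(sig, noise) {
  rn <- rmsAmplitude(noise)
  if (rn == 0)
    stop("noise has zero RMS; use the no-noise sentinel (NA), not an SNR")
  20 * log10(rmsAmplitude(sig) / rn)
}

#' Noise scaling factor for a target relative SNR
#'
#' `m = (RMSs / RMSn) * 10^(-targetSnrDb / 20)`, such that
#' `relativeSnr(sig, m * noise)` equals `targetSnrDb` to floating-point
#' accuracy. The no-noise sentinel (`NA`) yields `m = 0`.
#'
#' @inheritParams relativeSnr
#' @param targetSnrDb target relative SNR in dB, or `NA` for no added
#'   noise.
#' @return The dimensionless scaling factor `m >= 0`.
#' @export
scalingFactor <- function(sig, noise, targetSnrDb) {
  if (is.na(targetSnrDb)) return(0)
  rn <- rmsAmplitude(noise)
  if (rn == 0)
    stop("noise has zero RMS; use the no-noise sentinel (NA), not an SNR")
  (rmsAmplitude(sig) / rn) * 10^(-targetSnrDb / 20)
}

#' Mix scaled noise into an ECG record at a target relative SNR
#'
#' Element-wise `sig + m * noise` with `m` from [scalingFactor()]. The two
#' records must share one sampling frequency. A noise trace shorter than
#' the signal is tiled end-to-end; a longer one is truncated (the MIT-BIH
#' Arrhythmia and Noise Stress Test records are nominally equal length, so
#' this path serves synthetic inputs).
#'
#' @inheritParams scalingFactor
#' @return An [EcgRecord-class] whose `recordId` encodes the source id and
#'   the target SNR, e.g. `"123+snr6.02dB"` or `"123+nonoise"`.
#' @export
mixNoise <- function(sig, noise, targetSnrDb) {
  stopifnot(is(sig, "EcgRecord"), is(noise, "EcgRecord"))
  if (samplingRate(sig) != samplingRate(noise))
    stop("sampling frequency mismatch: signal ", samplingRate(sig),
         " Hz vs noise ", samplingRate(noise), " Hz")
  id <- paste0(recordId(sig),
               if (is.na(targetSnrDb)) "+nonoise"
               else paste0("+snr", format(targetSnrDb), "dB"))
  if (is.na(targetSnrDb))
    return(EcgRecord(samples(sig), fs = samplingRate(sig), recordId = id,
                     channelIndex = sig@channelIndex))
  n <- nSamples(sig)
  nz <- samples(noise)
  if (length(nz) < n) nz <- rep_len(nz, n) else nz <- nz[seq_len(n)]
  m <- scalingFactor(sig, noise, targetSnrDb)
  EcgRecord(samples(sig) + m * nz, fs = samplingRate(sig), recordId = id,
            channelIndex = sig@channelIndex)
}

#' The tested grid of added-noise levels
#'
#' The 18 noise levels of the study protocol: the "no noise added" sentinel
#' followed by 17 RMS ratios from 10 down to 0.4, each with its relative
#' SNR `20*log10(ratio)` in dB.
#'
#' @return A data.frame with columns `level` (1-18), `rms_ratio` (NA for
#'   the sentinel) and `snr_db` (NA for the sentinel).
#' @export
snrGrid <- function() {
  ratio <- c(NA, 10, 9, 8, 7, 6, 5, 4, 3, 2,
             1.8, 1.6, 1.4, 1.2, 1, 0.8, 0.6, 0.4)
  data.frame(level = seq_along(ratio), rms_ratio = ratio,
             snr_db = 20 * log10(ratio))
}

#' Materialize a full record-by-SNR mixing grid
#'
#' Mixes every record with the noise trace at every SNR level of the grid
#' and returns the mixed records plus a manifest (record id, target SNR,
#' scaling factor m, RMSs, RMSn), one row per output.
#'
#' @param records named list of [EcgRecord-class] objects.
#' @param noise an [EcgRecord-class] noise trace.
#' @param snrDb numeric vector of target SNR levels in dB, `NA` meaning no
#'   added noise; defaults to the full 18-level grid of [snrGrid()].
#' @param outDir optional directory; when given, each mixed record is also
#'   written via [writeRecord()] as CSV and the manifest as
#'   `manifest.json`.
#' @return A list with `records` (list of mixed [EcgRecord-class], one per
#'   record x level) and `manifest` (data.frame).
#' @export
mixGrid <- function(records, noise, snrDb = snrGrid()$snr_db,
                    outDir = NULL) {
  stopifnot(length(records) > 0)
  rn <- rmsAmplitude(noise)
  out <- vector("list", length(records) * length(snrDb))
  man <- vector("list", length(out))
  k <- 0L
  for (rec in records) {
    rs <- rmsAmplitude(rec)
    for (t in snrDb) {
      k <- k + 1L
      mixed <- mixNoise(rec, noise, t)
      out[[k]] <- mixed
      man[[k]] <- data.frame(
        record_id = recordId(rec), noise_record_id = recordId(noise),
        noise_channel = noise@channelIndex,
        target_snr_db = t, m = scalingFactor(rec, noise, t),
        rms_signal = rs, rms_noise = rn)
      if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeRecord(mixed, file.path(outDir,
                                     paste0(recordId(mixed), ".csv")))
      }
    }
  }
  manifest <- do.call(rbind, man)
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         dataframe = "rows", na = "null", digits = NA)
  list(records = out, manifest = manifest)
}
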