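# WFDB record / MIT annotation I/O.
#
# Supports signal formats 212 (two 12-bit two's-complement samples packed in
# 3 bytes) and 16 (16-bit little-endian), which cover the MIT-BIH Arrhythmia
# and Noise Stress Test databases. Any path ending in ".csv" selects a
# plain-text dialect instead, so test fixtures need no binary files:
#   records:     '# key=value' metadata lines, then sample_index,value_mV
#   annotations: '# key=value' metadata lines, then sample_index,code

# PhysioBank annotation mnemonics indexed by numeric annotation type code.
.ANN_SYMBOLS <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",   #  1-10
  "j", "/", "Q", "~", "",  "|", "",  "s", "T", "*",   # 11-20
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",  # 21-30
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")",   # 31-40
  "r"                                                 # 41
)

# Standard WFDB beat-type codes; everything else (rhythm changes, artifact
# marks, waveform boundaries, ...) is a non-beat annotation.
.BEAT_CODES <- c("N", "L", "R", "B", "A", "a", "J", "S", "V", "r",
                 "F", "e", "j", "n", "E", "/", "f", "Q", "?")

.is_csv <- function(path) grepl("\\.csv$", path, ignore.case = TRUE)

.read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in metaLines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  meta
}

.parse_header <- function(headerPath) {
  if (!file.exists(headerPath))
    stop("header file not found: ", headerPath)
  lines <- readLines(headerPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    stop("cannot parse WFDB header ", headerPath, ": no record line")
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 4L)
    stop("cannot parse WFDB header record line: '", lines[1L], "'")
  recordName <- sub("/.*$", "", rec[1L])
  nSig <- suppressWarnings(as.integer(rec[2L]))
  fs <- suppressWarnings(as.numeric(sub("[/(].*$", "", rec[3L])))
  nSamp <- suppressWarnings(as.numeric(rec[4L]))
  if (is.na(nSig) || is.na(fs) || is.na(nSamp))
    stop("cannot parse WFDB header record line: '", lines[1L], "'")
  if (length(lines) < 1L + nSig)
    stop("WFDB header ", headerPath, " declares ", nSig,
         " signals but has ", length(lines) - 1L, " signal lines")
  sig <- vector("list", nSig)
  for (k in seq_len(nSig)) {
    ln <- trimws(lines[1L + k])
    f <- strsplit(ln, "\\s+")[[1L]]
    if (length(f) < 2L)
      stop("cannot parse WFDB header signal line: '", ln, "'")
    fmt <- sub("[x:+].*$", "", f[2L])
    gainField <- if (length(f) >= 3L) f[3L] else "200"
    gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", gainField)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- NA_real_
    bm <- regmatches(gainField, regexec("\\(([-0-9]+)\\)", gainField))[[1L]]
    if (length(bm) == 2L) baseline <- as.numeric(bm[2L])
    adcZero <- if (length(f) >= 5L)
      suppressWarnings(as.numeric(f[5L])) else 0
    if (is.na(adcZero)) adcZero <- 0
    if (is.na(baseline)) baseline <- adcZero
    sig[[k]] <- list(file = f[1L], format = fmt, gain = gain,
                     baseline = baseline)
  }
  list(recordName = recordName, nSig = nSig, fs = fs, nSamples = nSamp,
       signals = sig)
}

.decode_212 <- function(rawBytes, nValues) {
  nTriples <- length(rawBytes) %/% 3L
  if (2L * nTriples < nValues)
    stop("format-212 signal file truncated: need ", nValues,
         " samples, file holds ", 2L * nTriples)
  b <- as.integer(rawBytes[seq_len(3L * nTriples)])
  b0 <- b[seq(1L, by = 3L, length.out = nTriples)]
  b1 <- b[seq(2L, by = 3L, length.out = nTriples)]
  b2 <- b[seq(3L, by = 3L, length.out = nTriples)]
  s1 <- b0 + (b1 %% 16L) * 256L
  s2 <- b2 + (b1 %/% 16L) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- numeric(2L * nTriples)
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out[seq_len(nValues)]
}

.encode_212 <- function(adc) {
  if (length(adc) %% 2L) adc <- c(adc, 0L)
  s1 <- adc[c(TRUE, FALSE)]
  s2 <- adc[c(FALSE, TRUE)]
  s1 <- ifelse(s1 < 0L, s1 + 4096L, s1)
  s2 <- ifelse(s2 < 0L, s2 + 4096L, s2)
  b0 <- s1 %% 256L
  b1 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  b2 <- s2 %% 256L
  out <- integer(3L * length(s1))
  out[seq(1L, by = 3L, length.out = length(s1))] <- b0
  out[seq(2L, by = 3L, length.out = length(s1))] <- b1
  out[seq(3L, by = 3L, length.out = length(s1))] <- b2
  as.raw(out)
}

#' Read one channel of a WFDB (or CSV) ECG record
#'
#' Reads a WFDB header plus its companion signal file and returns the
#' selected channel converted to physical millivolts via the header's gain
#' and baseline. Signal formats 212 and 16 are supported; any other storage
#' format raises an error rather than being misread. A path ending in
#' `.csv` is read in the package's plain-text dialect instead (metadata in
#' `# key=value` lines, then `sample_index,value_mV` rows).
#'
#' @param headerPath path to the `.hea` file (or `.csv` fixture).
#' @param channel 1-based channel to extract; default 1, the upper channel.
#' @return An [EcgRecord-class].
#' @seealso [writeRecord()], [readAnnotations()]
#' @export
readRecord <- function(headerPath, channel = 1L) {
  if (.is_csv(headerPath)) return(.read_record_csv(headerPath))
  hdr <- .parse_header(headerPath)
  channel <- as.integer(channel)
  if (channel < 1L || channel > hdr$nSig)
    stop("channel ", channel, " out of range: record has ", hdr$nSig,
         " channel(s)")
  sig <- hdr$signals[[channel]]
  datPath <- file.path(dirname(headerPath), sig$file)
  if (!file.exists(datPath))
    stop("signal file not found: ", datPath)
  nValues <- hdr$nSig * hdr$nSamples
  rawBytes <- readBin(datPath, what = "raw", n = file.size(datPath))
  adc <- switch(sig$format,
    "212" = .decode_212(rawBytes, nValues),
    "16" = {
      vals <- readBin(rawBytes, what = "integer", n = length(rawBytes) %/% 2L,
                      size = 2L, signed = TRUE, endian = "little")
      if (length(vals) < nValues)
        stop("format-16 signal file truncated: need ", nValues,
             " samples, file holds ", length(vals))
      vals[seq_len(nValues)]
    },
    stop("unsupported WFDB signal format '", sig$format,
         "' (only formats 212 and 16 are supported)")
  )
  # samples are interleaved across channels
  chan <- adc[seq(channel, by = hdr$nSig, length.out = hdr$nSamples)]
  mv <- (chan - sig$baseline) / sig$gain
  EcgRecord(mv, fs = hdr$fs, recordId = hdr$recordName,
            channelIndex = channel)
}

.read_record_csv <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("sample_index", "value_mV") %in% names(df)))
    stop("CSV record dialect requires columns sample_index,value_mV in ",
         path)
  df <- df[order(df$sample_index), ]
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs) else 360
  EcgRecord(df$value_mV, fs = fs,
            recordId = if (!is.null(meta$record_id)) meta$record_id
                       else sub("\\.csv$", "", basename(path)),
            channelIndex = if (!is.null(meta$channel))
              as.integer(meta$channel) else 1L)
}

#' Write an ECG record as WFDB format 212 (or CSV)
#'
#' Writes a header plus a format-212 signal file such that [readRecord()]
#' recovers the samples to within one ADC quantum (1/gain mV). A `path`
#' ending in `.csv` writes the plain-text dialect instead.
#'
#' @param rec an [EcgRecord-class]; amplitudes must stay within the 12-bit
#'   ADC range after applying `gain` (an error names the first offending
#'   sample otherwise).
#' @param path output path: a `.hea` header path (the `.dat` companion is
#'   written next to it) or a `.csv` path.
#' @param gain ADC gain in units per mV; default 200 as in the MIT-BIH
#'   databases.
#' @return The path written (header or CSV), invisibly usable for
#'   [readRecord()].
#' @export
writeRecord <- function(rec, path, gain = 200) {
  stopifnot(is(rec, "EcgRecord"))
  if (nSamples(rec) == 0L)
    stop("cannot write a zero-length record")
  if (.is_csv(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# record_id=", recordId(rec)),
                 paste0("# fs=", format(samplingRate(rec))),
                 paste0("# channel=", rec@channelIndex),
                 "sample_index,value_mV"), con)
    writeLines(paste(seq_along(samples(rec)) - 1L,
                     format(samples(rec), trim = TRUE, digits = 15),
                     sep = ","), con)
    return(path)
  }
  adc <- as.integer(round(samples(rec) * gain))
  bad <- which(adc > 2047L | adc < -2048L)
  if (length(bad))
    stop("amplitude exceeds the 12-bit ADC range after gain ", gain,
         " at sample index ", bad[1L] - 1L,
         " (", format(samples(rec)[bad[1L]]), " mV)")
  headerPath <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  base <- sub("\\.hea$", "", basename(headerPath))
  datName <- paste0(base, ".dat")
  n <- length(adc)
  writeLines(c(
    paste(base, 1L, format(samplingRate(rec)), n),
    paste0(datName, " 212 ", format(gain), "(0)/mV 12 0 ", adc[1L],
           " 0 0 ECG")
  ), headerPath)
  writeBin(.encode_212(adc), file.path(dirname(headerPath), datName))
  headerPath
}

#' Read a MIT-format (or CSV) beat annotation file
#'
#' Parses the MIT annotation byte format: a stream of 16-bit little-endian
#' words whose top 6 bits carry the annotation type code and bottom 10 bits
#' the sample interval from the previous annotation, with the extended-code
#' escapes SKIP (59, 4-byte interval), NUM/SUB/CHN (60-62, attribute
#' modifiers) and AUX (63, string). A truncated stream or an unknown type
#' code raises an error reporting the byte offset. A `.csv` path is read in
#' the plain-text dialect (`sample_index,code`).
#'
#' @param annotationPath path to the `.atr` (or any MIT annotation) file,
#'   or a `.csv` fixture.
#' @return A [BeatAnnotations-class] with `isBeatOnly(x) == FALSE`; codes
#'   are preserved verbatim, ordered by sample index.
#' @export
readAnnotations <- function(annotationPath) {
  if (.is_csv(annotationPath)) {
    meta <- .read_meta(annotationPath)
    df <- utils::read.csv(annotationPath, comment.char = "#",
                          colClasses = c("integer", "character"))
    if (!all(c("sample_index", "code") %in% names(df)))
      stop("CSV annotation dialect requires columns sample_index,code in ",
           annotationPath)
    df <- df[order(df$sample_index), ]
    return(BeatAnnotations(df$sample_index, df$code,
      recordId = if (!is.null(meta$record_id)) meta$record_id
                 else sub("\\.[^.]*$", "", basename(annotationPath))))
  }
  if (!file.exists(annotationPath))
    stop("annotation file not found: ", annotationPath)
  b <- as.integer(readBin(annotationPath, what = "raw",
                          n = file.size(annotationPath)))
  nWords <- length(b) %/% 2L
  times <- integer(0)
  codes <- character(0)
  time <- 0L
  w <- 1L  # word counter (1-based); byte offset of word w is 2*(w-1)
  word_at <- function(w) b[2L * w - 1L] + 256L * b[2L * w]
  while (w <= nWords) {
    off <- 2L * (w - 1L)
    word <- word_at(w)
    typeCode <- word %/% 1024L
    interval <- word %% 1024L
    if (typeCode == 0L) {
      if (interval == 0L) break  # end of stream
      stop("unknown annotation type code 0 with non-zero interval at byte ",
           "offset ", off)
    } else if (typeCode == 59L) {  # SKIP: 4-byte interval, high word first
      if (w + 2L > nWords)
        stop("truncated annotation stream: SKIP at byte offset ", off,
             " lacks its 4-byte interval")
      time <- time + word_at(w + 1L) * 65536L + word_at(w + 2L)
      w <- w + 3L
    } else if (typeCode %in% c(60L, 61L, 62L)) {  # NUM / SUB / CHN
      w <- w + 1L
    } else if (typeCode == 63L) {  # AUX: interval = byte count of string
      nAux <- interval + interval %% 2L
      w <- w + 1L + nAux %/% 2L
    } else if (typeCode <= 41L && nzchar(.ANN_SYMBOLS[typeCode])) {
      time <- time + interval
      times <- c(times, time)
      codes <- c(codes, .ANN_SYMBOLS[typeCode])
      w <- w + 1L
    } else {
      stop("unknown annotation type code ", typeCode, " at byte offset ",
           off)
    }
  }
  BeatAnnotations(times, codes,
    recordId = sub("\\.[^.]*$", "", basename(annotationPath)))
}

#' Keep only beat annotations
#'
#' Retains entries whose code is in the standard WFDB beat-code set
#' (`N L R B A a J S V r F e j n E / f Q ?`), dropping rhythm changes,
#' signal-quality marks and other non-beat annotations. Idempotent and
#' order-preserving.
#'
#' @param ann a [BeatAnnotations-class].
#' @return A [BeatAnnotations-class] with `isBeatOnly(x) == TRUE`.
#' @export
filterBeatAnnotations <- function(ann) {
  stopifnot(is(ann, "BeatAnnotations"))
  keep <- annCode(ann) %in% .BEAT_CODES
  BeatAnnotations(sampleIndex(ann)[keep], annCode(ann)[keep],
                  recordId = recordId(ann), beatOnly = TRUE)
}

#' Write beat annotations in the CSV dialect
#'
#' Companion to [readAnnotations()] for building plain-text fixtures and
#' persisting ground truth from the synthetic generator.
#'
#' @param ann a [BeatAnnotations-class].
#' @param path output `.csv` path.
#' @return `path`.
#' @export
writeAnnotationsCsv <- function(ann, path) {
  stopifnot(is(ann, "BeatAnnotations"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# record_id=", recordId(ann)), "sample_index,code"),
             con)
  writeLines(paste(sampleIndex(ann), annCode(ann), sep = ","), con)
  path
}
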