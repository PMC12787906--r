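# Shared fixtures and independent oracles for the test suite.

# Brute-force maximum-cardinality matching between sorted reference and
# detection vectors under an inclusive tolerance. Exhaustive recursion,
# independent of the greedy implementation; only for tiny instances.
oracle_max_matching <- function(refs, dets, dtt) {
  if (!length(refs) || !length(dets)) return(0L)
  best <- oracle_max_matching(refs[-1], dets, dtt)
  for (j in seq_along(dets)) {
    if (abs(dets[j] - refs[1]) <= dtt)
      best <- max(best, 1L + oracle_max_matching(refs[-1], dets[-j], dtt))
  }
  best
}

# A clean, regular synthetic record shared across detector tests.
clean_ecg <- function(durationS = 30, rrS = 0.7, seed = 2) {
  nBeats <- floor(durationS / rrS) + 2L
  suppressMessages(
    syntheticEcg(durationS = durationS, rrIntervals = rep(rrS, nBeats),
                 baselineAmplitudeMv = 0, tWaveAmplitudeMv = 0, seed = seed)
  )
}

# Encode beat annotations in the MIT 2-byte interval format (simple codes
# only), for parser tests. `codes` are numeric annotation type codes.
encode_mit_annotations <- function(sampleIndex, typeCodes, path) {
  prev <- 0L
  words <- integer(0)
  for (k in seq_along(sampleIndex)) {
    interval <- sampleIndex[k] - prev
    stopifnot(interval >= 0, interval < 1024)
    words <- c(words, bitwOr(bitwShiftL(typeCodes[k], 10), interval))
    prev <- sampleIndex[k]
  }
  words <- c(words, 0L)
  writeBin(as.integer(words), path, size = 2, endian = "little")
  path
}
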