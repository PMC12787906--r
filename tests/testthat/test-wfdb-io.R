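# WFDB record / MIT annotation reading and writing.

test_that("a hand-built format-212 block decodes 12-bit two's complement", {
  td <- withr::local_tempdir()
  hea <- file.path(td, "h212.hea")
  writeLines(c("h212 1 360 2", "h212.dat 212 200(0)/mV 12 0 1 0 0 ECG"),
             hea)
  # samples +1 and -1: bytes 0x01, 0xF0 (low nibble of +1, high nibble of
  # 4095), 0xFF
  writeBin(as.raw(c(0x01, 0xF0, 0xFF)), file.path(td, "h212.dat"))
  rec <- readRecord(hea)
  expect_equal(samples(rec), c(0.005, -0.005))
  expect_equal(samplingRate(rec), 360)
})

test_that("baseline and gain from the header drive physical conversion", {
  td <- withr::local_tempdir()
  hea <- file.path(td, "b.hea")
  # baseline 1024 as in the MIT-BIH databases; adc value 1025 -> +1 quantum
  writeLines(c("b 1 360 2", "b.dat 212 200(1024)/mV 12 1024 1025 0 0 ECG"),
             hea)
  writeBin(as.raw(c(0x01, 0x44, 0x00)), file.path(td, "b.dat"))  # 1025, 1024
  rec <- readRecord(hea)
  expect_equal(samples(rec), c(0.005, 0))
})

test_that("format-212 write/read round-trips within one ADC quantum", {
  td <- withr::local_tempdir()
  set.seed(11)
  x <- rnorm(1001, sd = 1.5)
  rec <- EcgRecord(x, fs = 360, recordId = "rt")
  p <- writeRecord(rec, file.path(td, "rt.hea"))
  back <- readRecord(p)
  expect_lte(max(abs(samples(back) - x)), 1 / 200)
  expect_equal(nSamples(back), 1001L)
  expect_identical(recordId(back), "rt")
})

test_that("a constant-zero record decodes exactly to baseline", {
  td <- withr::local_tempdir()
  p <- writeRecord(EcgRecord(numeric(100), fs = 360), file.path(td, "z.hea"))
  expect_identical(samples(readRecord(p)), numeric(100))
})

test_that("writer rejects degenerate and out-of-range input", {
  td <- withr::local_tempdir()
  expect_error(writeRecord(EcgRecord(numeric(0), fs = 360),
                           file.path(td, "e.hea")), "zero-length")
  # sample index of the first clipping amplitude is named (0-based)
  expect_error(
    writeRecord(EcgRecord(c(0, 0, 99), fs = 360), file.path(td, "c.hea")),
    "12-bit.*sample index 2")
})

test_that("two-channel interleaved 212 records honour channel selection", {
  td <- withr::local_tempdir()
  hea <- file.path(td, "two.hea")
  writeLines(c("two 2 360 2",
               "two.dat 212 200(0)/mV 12 0 10 0 0 ch1",
               "two.dat 212 200(0)/mV 12 0 20 0 0 ch2"), hea)
  # interleaved adc: t0 -> (10, 20), t1 -> (30, 40)
  adc <- c(10L, 20L, 30L, 40L)
  b <- qrsbench:::.encode_212(adc)
  writeBin(b, file.path(td, "two.dat"))
  expect_equal(samples(readRecord(hea, channel = 1)), c(10, 30) / 200)
  expect_equal(samples(readRecord(hea, channel = 2)), c(20, 40) / 200)
  expect_error(readRecord(hea, channel = 3), "out of range")
})

test_that("format 16 is read and other formats raise explicitly", {
  td <- withr::local_tempdir()
  hea16 <- file.path(td, "f16.hea")
  writeLines(c("f16 1 250 3", "f16.dat 16 100(0)/mV 16 0 -5 0 0 ECG"),
             hea16)
  writeBin(c(-5L, 0L, 1000L), file.path(td, "f16.dat"), size = 2,
           endian = "little")
  rec <- readRecord(hea16)
  expect_equal(samples(rec), c(-0.05, 0, 10))
  hea8 <- file.path(td, "f80.hea")
  writeLines(c("f80 1 360 2", "f80.dat 80 200(0)/mV 12 0 0 0 0 ECG"), hea8)
  writeBin(as.raw(c(0, 0)), file.path(td, "f80.dat"))
  expect_error(readRecord(hea8), "unsupported WFDB signal format '80'")
})

test_that("corrupt or missing headers raise parse errors naming the line", {
  td <- withr::local_tempdir()
  expect_error(readRecord(file.path(td, "nope.hea")), "not found")
  bad <- file.path(td, "bad.hea")
  writeLines("bad_record_line", bad)
  expect_error(readRecord(bad), "bad_record_line")
  trunc <- file.path(td, "tr.hea")
  writeLines(c("tr 1 360 100", "tr.dat 212 200(0)/mV 12 0 0 0 0 ECG"),
             trunc)
  writeBin(as.raw(c(0, 0, 0)), file.path(td, "tr.dat"))
  expect_error(readRecord(trunc), "truncated")
})

test_that("hand-built MIT annotation streams parse to ordered entries", {
  td <- withr::local_tempdir()
  p <- encode_mit_annotations(c(100L, 400L), c(1L, 5L),
                              file.path(td, "t.atr"))
  ann <- readAnnotations(p)
  expect_equal(sampleIndex(ann), c(100L, 400L))
  expect_equal(annCode(ann), c("N", "V"))
  expect_false(isBeatOnly(ann))
})

test_that("empty annotation streams yield empty annotations", {
  td <- withr::local_tempdir()
  p0 <- file.path(td, "empty.atr")
  writeBin(integer(0), p0, size = 2)
  expect_length(readAnnotations(p0), 0L)
  pEnd <- file.path(td, "end.atr")
  writeBin(0L, pEnd, size = 2, endian = "little")
  expect_length(readAnnotations(pEnd), 0L)
})

test_that("SKIP escapes advance time and stream errors report offsets", {
  td <- withr::local_tempdir()
  # SKIP (code 59, interval 0) + 4-byte interval 70000 (high word first),
  # then a normal beat 100 samples later
  words <- c(bitwShiftL(59L, 10),
             70000L %/% 65536L, 70000L %% 65536L,
             bitwOr(bitwShiftL(1L, 10), 100L), 0L)
  p <- file.path(td, "skip.atr")
  writeBin(as.integer(words), p, size = 2, endian = "little")
  ann <- readAnnotations(p)
  expect_equal(sampleIndex(ann), 70100L)
  # truncated SKIP: byte offset reported
  pT <- file.path(td, "truncskip.atr")
  writeBin(as.integer(bitwShiftL(59L, 10)), pT, size = 2,
           endian = "little")
  expect_error(readAnnotations(pT), "byte offset 0")
  # unknown extended code is an error, not a skip
  pU <- file.path(td, "unk.atr")
  writeBin(as.integer(bitwShiftL(45L, 10)), pU, size = 2, endian = "little")
  expect_error(readAnnotations(pU), "unknown annotation type code 45")
})

test_that("non-beat codes are parsed verbatim and filtered on request", {
  td <- withr::local_tempdir()
  # N at 10, rhythm change '+' (28) at 50, V at 90
  p <- encode_mit_annotations(c(10L, 50L, 90L), c(1L, 28L, 5L),
                              file.path(td, "mix.atr"))
  ann <- readAnnotations(p)
  expect_equal(annCode(ann), c("N", "+", "V"))
  beats <- filterBeatAnnotations(ann)
  expect_equal(sampleIndex(beats), c(10L, 90L))
  expect_equal(annCode(beats), c("N", "V"))
  expect_true(isBeatOnly(beats))
})

test_that("filterBeatAnnotations is idempotent and can yield empty sets", {
  allBeat <- BeatAnnotations(c(5L, 50L), c("N", "V"))
  once <- filterBeatAnnotations(allBeat)
  twice <- filterBeatAnnotations(once)
  expect_equal(sampleIndex(once), sampleIndex(allBeat))
  expect_identical(sampleIndex(twice), sampleIndex(once))
  expect_identical(annCode(twice), annCode(once))
  noBeat <- BeatAnnotations(c(10L, 20L), c("~", "|"))
  expect_length(filterBeatAnnotations(noBeat), 0L)
})

test_that("the CSV dialect round-trips records and annotations", {
  td <- withr::local_tempdir()
  rec <- EcgRecord(c(0.1, -0.25, 0.5), fs = 360, recordId = "csvrec")
  p <- writeRecord(rec, file.path(td, "r.csv"))
  back <- readRecord(p)
  expect_equal(samples(back), samples(rec))
  expect_equal(samplingRate(back), 360)
  expect_identical(recordId(back), "csvrec")
  ann <- BeatAnnotations(c(3L, 700L), c("N", "V"), recordId = "csvrec")
  pa <- writeAnnotationsCsv(ann, file.path(td, "a.csv"))
  backA <- readAnnotations(pa)
  expect_equal(sampleIndex(backA), sampleIndex(ann))
  expect_equal(annCode(backA), annCode(ann))
})

test_that("simple annotation streams re-encode losslessly", {
  td <- withr::local_tempdir()
  idx <- c(7L, 130L, 412L, 1000L)
  codes <- c(1L, 5L, 8L, 2L)
  p <- encode_mit_annotations(idx, codes, file.path(td, "rt.atr"))
  ann <- readAnnotations(p)
  # re-encode what was parsed and compare byte streams
  symToCode <- c(N = 1L, V = 5L, A = 8L, L = 2L)
  p2 <- encode_mit_annotations(sampleIndex(ann),
                               unname(symToCode[annCode(ann)]),
                               file.path(td, "rt2.atr"))
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})
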