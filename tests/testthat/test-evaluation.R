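# Beat pairing and detection statistics.

test_that("identical sequences pair perfectly at any tolerance", {
  refs <- c(100, 500, 900)
  p <- pairWithTolerance(refs, refs, 0L)
  expect_equal(nrow(beatPairs(p)), 3L)
  expect_true(all(beatPairs(p)$jitter == 0))
  expect_length(fpIndices(p), 0L)
  expect_length(fnIndices(p), 0L)
})

test_that("the tolerance comparison is inclusive and one-to-one", {
  p <- pairWithTolerance(c(100, 500), c(130, 700), 31L)
  expect_equal(beatPairs(p),
               data.frame(ref = 100, det = 130, jitter = 30))
  expect_equal(fnIndices(p), 500L)
  expect_equal(fpIndices(p), 700L)
  # |130 - 100| = 30 <= 31 pairs; exactly at the boundary also pairs
  pb <- pairWithTolerance(100, 131, 31L)
  expect_equal(nrow(beatPairs(pb)), 1L)
  pc <- pairWithTolerance(100, 132, 31L)
  expect_equal(nrow(beatPairs(pc)), 0L)
  expect_error(pairWithTolerance(c(5, 1), c(1, 2), 3L), "sorted")
})

test_that("greedy pairing equals the exhaustive maximum matching on
           well-separated instances and never exceeds it", {
  set.seed(77)
  for (rep in 1:60) {
    dtt <- sample(1:15, 1)
    nR <- sample(0:6, 1)
    nD <- sample(0:6, 1)
    sep <- sample(c(TRUE, FALSE), 1)
    if (sep) {
      # spacing > 2*dtt between all beats
      refs <- sort(sample.int(40, nR)) * (2 * dtt + 2)
      dets <- sort(sample.int(40, nD)) * (2 * dtt + 2) +
        sample(-dtt:dtt, nD, replace = TRUE)
      dets <- sort(dets)
    } else {
      refs <- sort(sample.int(60, nR))
      dets <- sort(sample.int(60, nD))
    }
    tp <- nrow(beatPairs(pairWithTolerance(refs, dets, dtt)))
    opt <- oracle_max_matching(refs, dets, dtt)
    if (sep) expect_identical(tp, as.integer(opt))
    expect_lte(tp, opt)
  }
})

test_that("count conservation holds under randomized inputs", {
  set.seed(88)
  for (rep in 1:30) {
    refs <- sort(sample.int(5000, sample(0:40, 1)))
    dets <- sort(sample.int(5000, sample(0:40, 1)))
    p <- pairWithTolerance(refs, dets, sample(0:30, 1))
    expect_equal(nrow(beatPairs(p)) + length(fnIndices(p)), length(refs))
    expect_equal(nrow(beatPairs(p)) + length(fpIndices(p)), length(dets))
    expect_true(all(abs(beatPairs(p)$jitter) <= dttSamples(p)))
  }
})

test_that("TP is non-decreasing and DER non-increasing in the tolerance", {
  set.seed(99)
  refs <- sort(sample.int(20000, 60))
  dets <- sort(pmax(1, refs + round(rnorm(60, 10, 25))))
  dets <- sort(c(dets, sample.int(20000, 8)))
  tols <- dttGrid()
  tps <- ders <- numeric(length(tols))
  for (k in seq_along(tols)) {
    m <- detectionMetrics(pairWithTolerance(refs, dets, tols[k]))
    tps[k] <- m$TP
    ders[k] <- m$DER
  }
  expect_true(all(diff(tps) >= 0))
  expect_true(all(diff(ders) <= 0))
})

test_that("detection statistics follow their defining formulas", {
  m <- detectionMetrics(105118, fn = 4376, fp = 4469)
  expect_equal(m$TB, 109494)
  expect_equal(round(m$DER, 2), 8.08)
  expect_equal(round(m$Se, 2), 96.00)
  expect_equal(round(m$PPV, 2), 95.92)
  # DER can exceed 100%
  m2 <- detectionMetrics(14630, fn = 94864, fp = 94957)
  expect_equal(round(m2$DER, 2), 173.36)
  # perfect detection
  m3 <- detectionMetrics(50, fn = 0, fp = 0)
  expect_equal(c(m3$DER, m3$Se, m3$PPV, m3$F1), c(0, 100, 100, 100))
  expect_error(detectionMetrics(0, fn = 0, fp = 3), "undefined")
})

test_that("F1 is symmetric under swapping Se and PPV", {
  # swapping FN and FP swaps Se and PPV and must leave F1 unchanged
  a <- detectionMetrics(80, fn = 7, fp = 13)
  b <- detectionMetrics(80, fn = 13, fp = 7)
  expect_equal(a$F1, b$F1)
})

test_that("proximity pairing is mutual-nearest-neighbor without a cap", {
  ident <- pairByProximity(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ident$tpJf, 3L)
  expect_equal(ident$fpJf + ident$fnJf, 0L)
  # 490 is nearer to 500 than 480, so 480 is an unpaired detection
  prox <- pairByProximity(c(100, 500), c(120, 480, 490))
  expect_equal(prox$pairs$det, c(120, 490))
  expect_equal(prox$fpJf, 1L)
  expect_equal(prox$fnJf, 0L)
  none <- pairByProximity(c(1, 2, 3) * 100, numeric(0))
  expect_equal(none$fnJf, 3L)
  expect_equal(none$tpJf, 0L)
})

test_that("the jitter discount halves at 12 ms and decreases strictly", {
  expect_equal(jitterToScore(12), 0.5)
  expect_equal(jitterToScore(0), 1.0)
  expect_equal(jitterToScore(36), 0.25)
  xs <- seq(0, 200, by = 5)
  expect_true(all(diff(jitterToScore(xs)) < 0))
  expect_true(all(jitterToScore(xs) > 0 & jitterToScore(xs) <= 1))
  expect_error(jitterToScore(-1), "non-negative")
})

test_that("the JF benchmark composes counts and jitter", {
  refs <- c(1000, 1360, 1720)
  expect_equal(jfScore(refs, refs, fs = 360)$jf, 100)
  # constant shift: F1_JF stays 100, JF is discounted by f(shift in ms)
  k <- 9
  shifted <- jfScore(refs, refs + k, fs = 360)
  expect_equal(shifted$f1Jf, 100)
  expect_equal(shifted$meanAbsJitterMs, k * 1000 / 360)
  expect_equal(shifted$jf, 100 * jitterToScore(k * 1000 / 360))
  # hand-worked 3-beat instance with one extra detection:
  # refs 1000,1360,1720; dets 1004,1356,1500,1724 -> TP_JF=3, FP_JF=1,
  # jitters +4,-4,+4 -> mean 4 samples = 11.111 ms
  hand <- jfScore(refs, c(1004, 1356, 1500, 1724), fs = 360)
  expect_equal(hand$tpJf, 3L)
  expect_equal(hand$fpJf, 1L)
  expect_equal(hand$meanAbsJitterMs, 4 * 1000 / 360)
  f1 <- 2 * (3 / 4 * 100) * 100 / (3 / 4 * 100 + 100)
  expect_equal(hand$f1Jf, f1)
  expect_equal(hand$jf, f1 * 1 / (1 + (4 * 1000 / 360) / 12))
  expect_error(jfScore(c(100), numeric(0), fs = 360), "undefined")
})

test_that("jitter histograms use zero-aligned fixed-width bins", {
  mk <- function(jit) {
    refs <- seq_along(jit) * 1000
    pairWithTolerance(refs, refs + jit, 60L)
  }
  h0 <- jitterHistogram(mk(rep(0, 5)), 1L)
  expect_equal(h0, data.frame(center = 0, count = 5L))
  h3 <- jitterHistogram(mk(c(-1, 0, 1)), 1L)
  expect_equal(h3$center, c(-1, 0, 1))
  expect_equal(h3$count, rep(1L, 3))
  # constant-delay detector run gives a unimodal histogram at the delay
  syn <- clean_ecg(durationS = 20, rrS = 0.75)
  det <- detectEcg(syn$record)
  p <- pairWithTolerance(syn$annotations, det, 59L)
  h <- jitterHistogram(p, 1L)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(h$center[which.max(h$count)],
               unique(beatPairs(p)$jitter))
})

test_that("sample-to-millisecond conversion matches the tolerance table", {
  expect_equal(round(dttToMs(3, 360), 2), 8.33)
  expect_equal(round(dttToMs(35, 360), 2), 97.22)
  expect_equal(round(dttToMs(59, 360), 2), 163.89)
  expect_equal(dttToMs(0, 360), 0)
})
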