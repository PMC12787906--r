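---
title: "Methods: benchmarking a traced QRS detector under tolerance and noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking a traced QRS detector under tolerance and noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsbench)
```

## Scope and model

`qrsbench` quantifies the *temporal* quality of a QRS detector, not just
its hit rate. Two experimental axes are swept:

* **Detection time tolerance (DTT).** A detection pairs with a reference
  beat only if `|det − ref| ≤ DTT` samples. The studied grid is the 15 odd
  values 3, 7, …, 59 samples (`dttGrid()`), i.e. 8.33–163.89 ms at 360 Hz.
* **Relative SNR of added muscle noise.** Records are mixed with an
  EMG-like noise trace scaled by `m = (RMSs/RMSn)·10^(−tSNR/20)` so that
  `20·log10(RMSs / (m·RMSn))` hits the target exactly
  (`scalingFactor()`, `mixNoise()`). The grid (`snrGrid()`) is the
  "no noise added" sentinel plus 17 RMS ratios from 10 (20 dB) down to 0.4
  (−7.96 dB). The SNR is *relative* because the source records already
  contain intrinsic noise: RMS is computed over the full raw record, and no
  clean-signal power estimate is attempted. Consequently `m = 0` is
  represented by the sentinel (`NA`), never by an infinite dB value, and a
  zero-RMS noise trace is an error rather than a number.

Detection statistics follow the standard confusion formulas
(`detectionMetrics()`): `DER = (FP+FN)/(TP+FN)`, `Se = TP/(TP+FN)`,
`PPV = TP/(TP+FP)`, `F1 = 2·PPV·Se/(PPV+Se)`, all kept at full precision
internally and rounded to two decimals only for display. `TP + FN = 0`
raises an error — an undefined Se/DER is signalled, not returned as a
number. `TP + FP = 0` leaves PPV (and F1) as `NA` so that sweeps over
degenerate cells can proceed.

The jitter-discounted **JF benchmark** uses tolerance-free
mutual-nearest-neighbor pairing (`pairByProximity()`): a reference and a
detection pair iff each is the other's nearest label. The mean *absolute*
jitter Δ̄ over the matched pairs is converted to a factor
`f(Δ̄) = 1/(1 + Δ̄/12 ms)` and `JF = F1_JF · f(Δ̄)`. Two points were
genuinely open and are decided here:

* "average time distance" is read as the mean of **absolute** offsets (a
  signed mean would let early and late detections cancel, contradicting the
  idea of a jitter penalty);
* all unpaired labels count as FP_JF/FN_JF, including ones before the first
  or after the last matched pair — the "between two matched pairs" phrasing
  does not define the boundary case, and counting everything keeps
  `TP+FN = |refs|`, `TP+FP = |dets|` conservation exact. Equidistant ties
  break toward the earlier label, deterministically.

## The detector under test

The detector is a faithful reimplementation of the widely used
moving-window-integration (Pan-Tompkins family) algorithm, with its known
temporal quirks deliberately kept:

* **Preprocessing** (`preprocessEcg()`): order-1 Butterworth band-pass
  5–15 Hz run *causally* (never forward–backward), first difference,
  element-wise squaring, then a causal arithmetic moving average over
  `round(150 ms · fs)` samples (54 at 360 Hz) with a growing window during
  warm-up. No group-delay compensation is applied at any stage: the
  uncompensated delay — tens of samples at 360 Hz — is precisely the
  behavior whose jitter the benchmark measures.
* **Decision stage** (`detectBeats()`): every *strict* local maximum of the
  feature signal (`mwa[i−1] < mwa[i]` and `mwa[i+1] < mwa[i]`) is a
  candidate; a candidate becomes a beat label iff it exceeds the adaptive
  threshold and lies more than `0.3·fs` samples (300 ms, the extended
  refractory of the implementation under test) after the previous label.
  The strict inequalities are kept verbatim: a flat plateau yields no
  candidate, which is the ambiguity that shifts detections toward the end
  of the mwa plateau and makes added noise — by roughening the plateau —
  sometimes produce *earlier*, more accurate detections.
* **Thresholds**: the classic constants are adopted where the studied
  implementation does not restate them, and all of them are exposed in
  `detectorConfig()`: running signal/noise peaks smoothed with coefficient
  0.125 (accepted candidates update the signal peak, rejected ones the
  noise peak), threshold at 0.25 of the way from the noise to the signal
  peak, searchback triggered when the elapsed interval exceeds 1.66× the
  mean of the last 8 RR intervals, with a halved threshold.
* **Initialization**: the running peaks are seeded from the maximum and the
  mean of the feature signal over the first 2 s, and detections are
  suppressed during the first 300 ms (implemented by initializing the
  refractory state, so the trace invariant below stays exact). Both choices
  are data-driven, which preserves an exact invariance: scaling the input
  by any `c > 0` scales the feature signal by `c²` and every threshold with
  it, leaving the detections bit-identical (this is tested).
* **Searchback** emits the recovered candidate *retroactively* as a beat
  label (flagged `searchback` in the trace) rather than only adjusting
  thresholds; whether the original does the former or the latter is not
  documented, and retroactive emission is the variant that affects the
  counted statistics, so it is the one worth tracing. The signal peak is
  updated with the classic 0.25 searchback coefficient.

The full decision trace (`decisionTrace()`, `traceWindow()`) records, per
candidate, the four booleans and the threshold in force, and replaying the
trace alone reproduces the beat labels exactly. For every directly accepted
candidate, `accepted ⇔ rising ∧ falling ∧ above ∧ outside_refractory`
holds by construction; searchback emissions are the flagged exception
(their `above_threshold` was false at decision time — that is why they
needed recovering).

The exact filter design of the studied implementation (order, topology) is
not published; the order-1 5–15 Hz causal choice is this package's
documented decision, and every filter and threshold constant is
configurable so the trace can be matched against other implementations
empirically.

## Pairing: greedy with a proven-optimal regime

`pairWithTolerance()` accepts candidate pairs in ascending `|Δ|`, breaking
ties toward the earlier reference, then the earlier detection. The
comparison is inclusive (`|Δ| ≤ DTT`, reading "must not exceed"
literally). Greedy matching is deterministic and order-independent, and it
equals the maximum-cardinality bipartite matching whenever consecutive
beats are more than `2·DTT` apart — always true for the studied grid
(DTT ≤ 59) against the detector's refractory (> 108 samples) and the
generator's RR floor. The test suite verifies both halves against an
exhaustive matching oracle on small instances: equality under separation,
and never exceeding the optimum without it.

## Synthetic data: what it emulates and what it does not

`syntheticEcg()` emulates the *sampling conventions* of the reference
databases — 360 Hz, single channel, millivolt amplitudes, 0-based sample
indices, beat annotations at exact QRS centers — with a Gaussian QRS
template (SD = width/5, default visible width 80 ms, amplitude 1 mV), an
optional opposite-sign T wave 300 ms later, sinusoidal baseline wander
(0.1 mV at 0.3 Hz, respiration-like), and RR intervals of mean 0.8 s with
0.04 s jitter floored at 0.25 s. `syntheticMuscleNoise()` produces
band-limited Gaussian noise (order-2 Butterworth, default 15–110 Hz — a
band chosen to overlap the detector's 5–15 Hz passband so added noise
genuinely perturbs the feature signal) rescaled to an exact target RMS.
All randomness flows through explicit seeds; the global RNG state is saved
and restored.

What passing tests on this data show: the plumbing, the decision stage, the
pairing and the pooling are correct, and the qualitative phenomena (large
constant detection delay on clean records, DER collapse under tightened
DTT, noise-induced earlier detections) are reproduced. What they do not
show: performance on real arrhythmia morphologies (ectopy, bundle-branch
blocks, paced beats), real electrode artifacts, or the exact pooled DER
values of the reference databases — those require the accession, and the
corresponding acceptance check activates only when a local copy is present
(`QRSBENCH_MITDB`).

## Sweep orchestration and pooling

`runSweep()` factorizes the sweep: detection depends on the noise level but
not on the tolerance, so the detector runs once per (record, SNR) and the
cached detections are re-paired per DTT. Pooled statistics are computed by
summing TP/FN/FP over records first and applying the formulas to the sums —
never by averaging per-record percentages; the two differ and the tests
include a hand-arithmetic case distinguishing them. `TP/TB` is emitted
alongside DER so both historical efficiency measures are available.
`perRecordDerDiff()` compares two sweep cells per record (noise-vs-no-noise
at fixed DTT, or two DTTs at fixed noise), signed so that a positive value
means the second condition lowers the DER.

## Numerical and convention notes

* Sample indices are 0-based from record start everywhere, so published
  sample numbers can be used verbatim; the `channel` argument of
  `readRecord()` is 1-based as natural in R, defaulting to channel 1 (the
  "upper" channel).
* `dttToMs()` keeps full precision; 35 samples at 360 Hz is 97.22 ms
  (some published tables print 97.23, and 59 samples appears as both
  163.89 and 163.90 — the computed values 97.22/163.89 are used
  everywhere).
* WFDB support covers signal formats 212 and 16, which suffice for the
  target databases; anything else raises an explicit unsupported-format
  error rather than risking a silent misread. The writer refuses amplitudes
  that would clip the 12-bit range, naming the first offending sample.
  Round-trips are exact to one ADC quantum (1/gain mV).
* The MIT annotation parser fails loudly: truncated streams and unknown
  type codes report the byte offset instead of skipping.
* The test suite and examples use records of 10–60 s and mini-databases of
  two records — sizes chosen so the full suite exercises every code path,
  including half a dozen full detector runs and a complete 15-DTT sweep, in
  a few seconds while remaining statistically meaningful (dozens of beats
  per record).

## Known limitations

* The detector reproduces the *family* of the studied implementation; with
  unpublished filter internals, per-sample agreement with any specific
  binary is a matter of matching `detectorConfig()` empirically via the
  trace.
* Proximity pairing is mutual-nearest-neighbor; alternative chain-matching
  definitions of the JF counts could differ on pathological instances
  (dense false positives between beats).
* The noise generator is stationary Gaussian; real muscle artifact is
  bursty and non-stationary, so noise-robustness results on synthetic data
  are indicative, not definitive.
* Multi-segment WFDB records, variable-layout headers and annotation
  *writing* in the binary format are out of scope.
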