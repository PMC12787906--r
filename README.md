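# qrsbench

Benchmarking a QRS detector under tightened timing tolerance and
controlled muscle-artifact noise.

## The problem

QRS detection — locating the R peak of every heartbeat in an ECG — is the
first step of almost any automated ECG analysis. Detectors are usually
ranked by their confusion statistics against reference annotations:

- **Se** = TP / (TP + FN), **PPV** = TP / (TP + FP),
  **F1** = 2·PPV·Se / (PPV + Se),
- **DER** = (FP + FN) / (TP + FN), the detection error rate, which can
  exceed 100% when false positives are numerous.

A detection only counts as a true positive if it falls within a **detection
time tolerance (DTT)** of a reference beat. Published comparisons often use
a generous tolerance (e.g. 150 ms), which hides how *temporally unstable* a
detector's fiducial points are — and that instability is what matters for
downstream time-series analyses such as heart-rate variability. `qrsbench`
measures exactly this: how the statistics of a widely used
moving-window-integration (Pan-Tompkins style) detector degrade as

1. the DTT is tightened over a 15-level grid from 59 down to 3 samples
   (163.89 ms to 8.33 ms at 360 Hz), and
2. muscle-artifact (EMG-like) noise is mixed into the ECG at 18 controlled
   **relative SNR** levels, `SNR = 20·log10(RMS_signal / RMS_noise)` dB,
   from "no noise added" through 20 dB down to −7.96 dB, where the noise is
   scaled by `m = (RMS_s / RMS_n) · 10^(−tSNR/20)` before mixing
   `ECG + m·noise`.

Alongside the tolerance-windowed statistics, the package computes the
**JF benchmark**: an F1 score from tolerance-free mutual-nearest-neighbor
pairing, discounted by the mean absolute jitter Δ̄ between detections and
references through `f(Δ̄) = 1 / (1 + Δ̄ / 12 ms)` (so 12 ms of average
jitter halves the score), `JF = F1_JF · f(Δ̄)`.

The detector under test is reimplemented with a **full decision-stage
trace**: every candidate peak of the feature signal is recorded with its
four acceptance conditions (rising slope, falling slope, above the adaptive
threshold, outside the 300 ms refractory period), so pathological behaviors
— in particular the strict local-maximum test on the plateaus of the
moving-window-averaged feature signal, which delays detections by tens of
samples and lets *added noise paradoxically reduce the DER* — can be
inspected candidate by candidate.

## What is in the package

| Area | Functions |
| --- | --- |
| WFDB I/O (formats 212/16, MIT annotations, CSV dialect) | `readRecord`, `writeRecord`, `readAnnotations`, `filterBeatAnnotations`, `writeAnnotationsCsv` |
| Synthetic data with ground truth | `syntheticEcg`, `syntheticMuscleNoise` |
| Relative-SNR noise mixing | `rmsAmplitude`, `relativeSnr`, `scalingFactor`, `mixNoise`, `mixGrid`, `snrGrid` |
| Traced detector | `detectorConfig`, `preprocessEcg`, `detectBeats`, `detectEcg`, `traceWindow` |
| Evaluation | `pairWithTolerance`, `detectionMetrics`, `pairByProximity`, `jitterToScore`, `jfScore`, `jitterHistogram`, `dttToMs` |
| Sweep orchestration | `dttGrid`, `runSweep`, `perRecordDerDiff`, `reportSweep` |

A thin command-line front end (`mix`, `detect`, `evaluate`, `bench`
subcommands) lives in `inst/scripts/qrsbench.R`.

## Worked example

```r
library(qrsbench)

syn <- syntheticEcg(durationS = 60, seed = 42)       # ground-truth beats
ma  <- syntheticMuscleNoise(durationS = 60, seed = 7) # EMG-like noise
noisy <- mixNoise(syn$record, ma, 6.02)               # relative SNR 6.02 dB
det  <- detectEcg(noisy)

for (tol in c(59L, 35L, 31L, 3L)) {
  m <- detectionMetrics(pairWithTolerance(syn$annotations, det, tol))
  cat(sprintf("DTT %2d (%6.2f ms): Se %6.2f  PPV %6.2f  DER %6.2f\n",
              tol, dttToMs(tol, 360), m$Se, m$PPV, m$DER))
}
jf <- jfScore(syn$annotations, det, fs = 360)
cat(sprintf("JF = %.2f%% (mean |jitter| %.1f ms)\n", jf$jf,
            jf$meanAbsJitterMs))
```

prints

```
DTT 59 (163.89 ms): Se 100.00  PPV  98.67  DER   1.35
DTT 35 ( 97.22 ms): Se  95.95  PPV  94.67  DER   9.46
DTT 31 ( 86.11 ms): Se  94.59  PPV  93.33  DER  12.16
DTT  3 (  8.33 ms): Se  45.95  PPV  45.33  DER 109.46
JF = 29.49% (mean |jitter| 28.4 ms)
```

Reading: the detector finds essentially every beat at the widest tolerance,
but its detection points lag the true R peaks by tens of samples, so the
DER explodes as the tolerance tightens — at 3 samples more detections miss
the window than hit it (DER > 100%). The JF score makes the same point in a
single number: near-perfect pairing (F1_JF ≈ 99%) discounted to ~29% by a
28 ms average jitter. On the clean record the same pipeline is delayed by a
constant 40 samples; mixing noise at 6.02 dB moves the median detection
13 samples after the reference — earlier, not later, which is exactly the
plateau effect the decision trace (`decisionTrace(det)`,
`traceWindow(det, start, end)`) lets you inspect.

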