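Package: qrsbench
Title: Benchmarking QRS Detectors Under Tightened Timing Tolerance and
    Controlled Muscle-Artifact Noise
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to measure how the detection statistics of a QRS detector
    degrade as the allowed temporal tolerance between detected and reference
    beats is tightened and as muscle-artifact noise is mixed into the ECG at
    controlled relative signal-to-noise ratios. Includes a reader and writer
    for WFDB format-212/16 records and MIT annotation files plus a plain-text
    CSV dialect; a synthetic ECG and EMG-noise generator with known R-peak
    ground truth; RMS-based relative-SNR noise mixing; a fully traced
    reimplementation of a moving-window-integration (Pan-Tompkins style)
    beat detector whose decision stage can be inspected candidate by
    candidate; tolerance-parameterized one-to-one beat pairing with DER, Se,
    PPV and F1 statistics and the jitter-discounted JF benchmark; and an
    orchestrator for full tolerance-by-SNR sweeps with pooled-count
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
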