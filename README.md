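# gcgbeat

ECG-free heartbeat detection in gyrocardiography (GCG) signals by
template matching, with the full ECG-referenced evaluation protocol.

## What problem this solves, and for whom

A gyroscope on the chest records the tiny angular velocities produced by
the heart's twisting motion. In the 7–30 Hz band each heartbeat shows up
as a systolic oscillatory complex (whose dominant peak marks aortic
valve opening, the AO peak) followed by a smaller diastolic complex.
Detecting individual heartbeats in this signal *without* a simultaneous
ECG makes unobtrusive long-term heart-rate monitoring possible; the
difficulty is low SNR and strong morphological variability.

gcgbeat is for researchers in cardio-mechanical monitoring
(gyro/seismocardiography) who need (a) a reproducible implementation of
the NCC template-matching detector, (b) the standard evaluation protocol
against reference ECG R peaks, and (c) a synthetic paired ECG+GCG
generator with exact ground truth for testing detectors end to end.

## The method

Given a single-beat template $w$ (length $m$) and signal $x$, the
detector computes the zero-normalized cross-correlation at every valid
alignment $i$:

$$NCC(i) = \frac{\sum_k (x_{i+k} - \bar x_i)(w_k - \bar w)}
  {\sqrt{\sum_k (x_{i+k} - \bar x_i)^2\; \sum_k (w_k - \bar w)^2}} \in [-1, 1]$$

Heartbeats are the local NCC maxima with topographic prominence ≥ 0.5
and pairwise spacing ≥ 500 ms, refined onto the local systolic maximum
of the band-passed waveform. Detections are scored per reference cardiac
cycle (R-to-R): a cycle with no detection is a false negative (FN),
extra in-cycle detections are false positives (FP), and a cycle whose
only detections are temporally implausible is a detection error (DE),
which counts against both metrics:

$$\text{Sensitivity} = \frac{TP}{TP+FN+DE}\cdot 100, \qquad
  PPV = \frac{TP}{TP+FP+DE}\cdot 100$$

Inter-beat intervals (consecutive R–R vs. consecutive detection times,
dropping intervals touched by FN/DE cycles) are compared by least-squares
regression, Pearson correlation, and Bland–Altman analysis
(bias ± 1.96 SD limits of agreement with 95% confidence intervals).

## Worked example

```r
library(gcgbeat)

cfg    <- synth_config(n_beats = 200, snr_db = 10, seed = 7)  # 10 dB SNR, 3 ms R-AO jitter
rec    <- synth_recording(cfg)$recording                      # channels: ecg, gcgy @ 1 kHz
report <- run_pipeline(pipeline_config(rec))                  # auto template selection
report
#> <pipeline_report>
#>   R peaks: 200   NCC peaks: 202
#> <detection_counts> TP=199 FP=0 FN=0 DE=0 (cycles=199)
#>   sensitivity: 100.0%   PPV: 100.0%   valid IBI pairs: 198
#> <agreement_report>
#>   n pairs     : 198
#>   slope       : 1.0052   intercept: -4.18 ms   R^2: 0.9920
#>   Pearson r   : 0.9960 (p = 1.45e-207)
#>   bias        : 0.025 ms (p = 0.934), 95% CI [-0.579, 0.629]
#>   LoA         : [-8.42, 8.47] ms
#>   95% CI LoA  : [-9.47, 9.52] ms
```

Reading this: all 199 reference cardiac cycles contained exactly one
plausible detection (the two extra NCC peaks fell in the signal-free
padding outside the R-peak span, so no cycle counts them). The paired
inter-beat intervals agree with the ECG reference with sub-0.1 ms bias
and ±8.4 ms limits of agreement — the irreducible floor set by the
generator's 3 ms beat-to-beat R-to-AO delay jitter
(±1.96·√2·3 ≈ ±8.3 ms), i.e. the detector adds almost no timing error
of its own.

Lower-level entry points mirror the processing chain:
`resample_linear()`, `preprocess_ecg()`/`preprocess_gcg()`,
`pan_tompkins()`, `select_template()`/`suggest_template()`, `ncc()`,
`detect_ncc_peaks()`, `detect_heartbeats()`, `annotate_beats()`,
`pair_valid_ibis()`, `agreement_report()`.

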