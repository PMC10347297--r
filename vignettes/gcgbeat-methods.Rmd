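---
title: "Heartbeat detection in gyrocardiography signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat detection in gyrocardiography signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gyrocardiography (GCG) records the angular velocities of the chest wall
produced by the twisting and untwisting of the heart, using a MEMS
gyroscope strapped or taped to the sternum. The component about the
cranio-caudal axis (GCGy) carries most of the cardiac rotational signal.
After band-pass filtering, each heartbeat appears as two oscillatory
bursts: a *systolic complex* whose dominant peak is associated with
aortic valve opening (the AO peak), and a smaller, later *diastolic
complex*. Locating individual heartbeats in GCG without a simultaneous
ECG enables unobtrusive, long-term heart-rate monitoring; the challenge
is the low signal-to-noise ratio and the considerable intra- and
inter-subject morphological variability of the signal.

gcgbeat implements a template-matching detector: a single representative
heartbeat segment is selected, the normalized cross-correlation (NCC)
between that template and every signal window is computed, and heartbeats
are reported at NCC local maxima subject to a minimum topographic
prominence (0.5) and a minimum mutual distance (500 ms). The package also
implements the ECG-referenced evaluation protocol used to validate such
detectors, and a synthetic paired ECG+GCG generator so the entire
pipeline can be exercised with exact ground truth.

## Processing chain

1. **Resampling.** Recordings (typically 256 or 512 Hz) are linearly
   interpolated to a 1 kHz working rate (`resample_linear()`), purely to
   refine the temporal resolution of fiducials. Linear interpolation has
   a known error bound of $h^2 \max|f''| / 8$ for step $h$; for cardiac
   in-band content at 256 Hz this is below 1% of amplitude, which is
   ample since filtering follows.
2. **Filtering.** ECG: 4th-order zero-phase Butterworth band-pass
   0.5–40 Hz followed by a 50 Hz comb notch. GCG: 4th-order zero-phase
   Butterworth band-pass 7–30 Hz, which retains both complexes while
   rejecting respiration and high-frequency noise. Zero phase matters:
   any phase distortion would bias fiducial timing, so every filter is
   applied forward–backward.
3. **Reference R peaks.** The classic Pan–Tompkins stages (5–15 Hz
   band-pass, five-point derivative, squaring, 150 ms moving-window
   integration, dual adaptive thresholds with 200 ms refractory period,
   360 ms T-wave slope discrimination, missed-beat search-back), with
   each fiducial refined to the local maximum of the band-passed ECG
   within ±40 ms.
4. **Template.** Manual (`select_template()`) or automatic
   (`suggest_template()`). The manual guideline: start two or three waves
   before the highest systolic peak, where wave amplitude is well below
   the systolic magnitude, and end after the last wave of the diastolic
   complex.
5. **NCC detection.** `ncc()` computes the zero-normalized
   cross-correlation at every valid alignment (local window mean removed,
   so the coefficient is bounded in $[-1, 1]$ and invariant to positive
   affine transforms of the signal); `detect_ncc_peaks()` keeps local
   maxima with prominence ≥ 0.5, greedily by descending height with
   ≥ 500 ms mutual spacing.
6. **Evaluation.** Detections are classified per reference R–R cycle
   (half-open windows): no peak → FN; a peak near the expected
   mechanical delay → TP, extra in-cycle peaks → FP; peaks present but
   none plausible → DE. Sensitivity $= 100\,TP/(TP+FN+DE)$ and PPV
   $= 100\,TP/(TP+FP+DE)$: a DE cycle is at once a missed beat and a
   spurious detection, so it enters both denominators (and is therefore
   tallied separately from FP and FN rather than folded into them).
   Inter-beat intervals are paired only across consecutive TP cycles and
   compared by ordinary least squares, Pearson correlation, and
   Bland–Altman analysis (classic 1986 formulation: LoA $=$ bias
   $\pm 1.96\,s_d$; CI of bias from $s_d/\sqrt n$; CI of each LoA from
   $s_d\sqrt{3/n}$, both with $t_{0.975,\,n-1}$).

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `target_fs` | 1000 | Hz | working rate after interpolation |
| ECG band | 0.5–40 | Hz | QRS conditioning before Pan–Tompkins |
| GCG band | 7–30 | Hz | retains systolic/diastolic complexes |
| notch base / q | 50 / 35 | Hz / – | powerline fundamental and tooth width |
| `min_prominence` | 0.5 | – | NCC peak prominence threshold |
| `min_distance_ms` | 500 | ms | refractory spacing of detections |
| `delay_tol_ms` | 150 | ms | plausibility window for TP vs DE |
| `refine_ms` | 40 | ms | NCC-detection waveform refinement window |

The prominence/distance pair is the method's core operating point; 500 ms
corresponds to a 120 bpm ceiling, appropriate for resting recordings.

## Design choices made where the design was open

**Beat-time convention and waveform refinement.** An NCC peak at
alignment $i$ is first reported at $i$ plus the template's
systolic-anchor offset (the index of its maximum-absolute sample), which
makes times comparable across templates. Raw NCC-alignment times,
however, inherit the beat-to-beat variability of the NCC-peak-to-AO
delay: when a beat's morphology deviates from the template, the best
whole-pattern alignment and the beat's own AO peak move apart, which
caps achievable inter-beat-interval agreement well before the R-to-AO
jitter floor. `detect_heartbeats()` therefore refines each detection
onto the local maximum of the band-passed GCG within ±40 ms — exactly
symmetric to the refinement applied to R peaks on the ECG side — so the
reported fiducial is the beat's own systolic (AO) peak. `refine_ms = 0`
restores raw NCC-alignment times.

**Zero-phase filtering in second-order sections.** "4th-order zero-lag
Butterworth" is read as: design a 4th-order filter, apply it
forward–backward (zero phase, effective 8th-order magnitude response) —
the `butter` + `filtfilt` idiom. Edge transients are handled by
odd-symmetric extension of length $3(n_{filt}-1)$ with steady-state
initial conditions. The filter itself is designed analytically in
second-order sections (low-pass prototype poles, band-pass
transformation, bilinear mapping): at a 0.5 Hz lower edge on a 1 kHz
rate, the expanded transfer-function polynomial is so ill-conditioned
that filtering visibly loses linearity, while the biquad cascade is
accurate to ~1e-11.

**Comb notch.** A cascade of zero-phase RBJ biquad notches at the
powerline fundamental and all harmonics below Nyquist, each with the
same absolute bandwidth `base_hz / q` (1.4 Hz at the defaults), which
attenuates every harmonic by well over 20 dB while leaving content a few
Hz away essentially untouched.

**Automatic template suggestion.** The manual guideline is
operationalized as: qualify the globally dominant positive peak
(requiring peak ≥ 10 × median |signal|, which separates quasi-periodic
beat trains, whose diastasis is quiet, from stationary noise); walk
backward over local extrema until amplitude falls below 30% of the
systolic magnitude and step back past one or two zero crossings; walk
forward on a smoothed amplitude envelope, take the first burst exceeding
20% of the systolic magnitude after the inter-complex gap as the
diastolic complex, and end one zero crossing after its trailing edge,
capped at `min(0.9 × median RR, 700 ms)` past the systolic peak. The
30%/20% thresholds are validated on synthetic data only; on real
recordings manual selection remains the reference procedure.

**DE operationalization.** The published protocol annotated detection
errors manually against the reference ECG. For reproducibility, gcgbeat
uses a fixed rule: the expected R-to-detection delay is the median signed
offset between each cycle's R peak and its nearest detection over the
record, and a cycle whose detections all fall outside ±150 ms of that
expected position is a DE.

## The synthetic generator

`synth_config()` / `synth_recording()` produce paired ECG+GCG recordings
with exact ground truth. The model and its defaults describe a resting
supine adult:

* RR intervals: Normal(800, 50) ms truncated at ±4 SD (white HRV; no
  autocorrelation). SDNN 50 ms is a standard short-term resting
  reference value.
* ECG: per beat a narrow positive R spike (Gaussian, σ = 10 ms) with
  small Q/S dips and P/T humps at fixed phase offsets; the R time is the
  spike apex sample, exactly.
* GCG: per beat, at R + delay (delay ~ Normal(100, 3) ms — the
  pre-ejection-period component that fundamentally limits ECG-vs-GCG
  interval agreement), a systolic burst (18 Hz carrier, 120 ms Hann
  envelope) followed by a diastolic burst (15 Hz, 100 ms, 60% relative
  amplitude, 320 ms after systolic onset). The carrier extremum is
  centred on the envelope maximum so each beat has a single dominant
  positive lobe: this is what makes the AO fiducial well defined — with
  a sine-phased carrier the two central lobes are nearly equal and the
  ground-truth "AO peak" flips between them under frequency jitter,
  which is a property no real systolic complex has.
* Variability: 5% per-beat jitter of burst amplitude and frequency;
  respiratory amplitude modulation (0.25 Hz, 20% depth); additive white
  Gaussian noise at 10 dB SNR relative to the clean signal RMS.

What the generator does **not** emulate: pathological morphologies
(valvular-disease waveform atlases), motion artifacts, posture changes,
baseline wander, autocorrelated heart-rate dynamics, or template drift
over long recordings. Passing the synthetic acceptance bar therefore
shows the pipeline's correctness and its behaviour under the modelled
variability — not clinical performance on real patients.

A consequence worth knowing: NCC between a ~600-sample 7–30 Hz template
and band-limited noise has standard deviation roughly
$(2BT)^{-1/2} \approx 0.18$, so prominence-0.5 peaks *do* occur in pure
noise segments. The prominence threshold controls the operating point;
it does not guarantee silence on beat-free signal. In evaluation this is
absorbed by the cycle-based FP/DE accounting.

## Numerical notes

* NCC is computed with an FFT cross term and running-sum window moments
  (signal globally centred first); windows whose variance falls below a
  cancellation-scaled guard ($8\,\varepsilon\, n \max x^2$) return 0 by
  convention. Agreement with a direct double-loop evaluation is ~1e-15
  on random inputs.
* Peak prominence is the standard topographic definition (height above
  the higher of the two bases reached before strictly higher ground or
  the series edge); retention under the distance constraint is greedy by
  descending height with earlier-index tie-break.
* Problem sizes used in the test-suite cohort: 20 records × 200 beats at
  1 kHz (~160 s each), which exercises every stage at full working rate.

## Worked example

```{r example}
library(gcgbeat)

cfg <- synth_config(n_beats = 200, snr_db = 10, seed = 7)
rec <- synth_recording(cfg)$recording
report <- run_pipeline(pipeline_config(rec))
report
```

## Known limitations

* Single fixed template per recording: no multi-template or adaptive
  tracking, no polarity inversion (negate the channel if the systolic
  peak is negative), no SCG/GCG sensor fusion.
* The DE rule is a reproducible proxy for a manual judgment; counts on
  real data will differ from manual annotation.
* Bland–Altman analysis pools all interval pairs; no repeated-measures
  (per-subject clustering) correction.
* The CSV recording format is a package convention; only a minimal
  delimited-text reader is provided (no EDF or proprietary formats).
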