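---
title: "Detecting and analysing nocturnal coughs from audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing nocturnal coughs from audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Coughing at night carries clinical information — about respiratory disease,
about sleep quality, and (through its distribution over sleep stages) about
how cough and sleep interact. Counting coughs by hand from a whole-night
recording is impractical, and contact sensors disturb the sleep being
measured. `noctcough` implements a complete non-contact pipeline: a
microphone recording goes in; detected, classified cough events and
per-sleep-stage cough rates come out.

The pipeline has five stages:

1. **Pre-processing.** DC removal and anti-aliased down-sampling to 16 kHz
   (all relevant spectral content of cough sounds lies below 8 kHz).
2. **Event detection.** Short-time energy `E(j) = sum x(i)^2` over 20 ms
   frames with 50% overlap. Three recording-adaptive thresholds are read
   off the histogram of frame energies (in dB): `th1` triggers an event,
   `th2` locates its onset scanning left, `th3` its offset scanning right
   (hysteresis). Events outside 0.15–1.1 s — the usual range of cough
   durations — are discarded.
3. **Feature extraction.** Each event is segmented into the cough's
   phases: the explosive first part (energy peak within the first
   0.079 s), the turbulent second part (from the first local energy
   minimum after the peak), and an optional voiced third part (first
   frame whose 50–255 Hz autocorrelation score exceeds 0.45). A
   34-dimensional vector is extracted: the energy-peak index, 12 MFCCs
   per part, voiced scores in the 50–255 Hz and 10–100 Hz bands,
   cross-frame LPC variance, the part-1/part-2 energy-peak ratio, mean
   zero-crossing rate, kurtosis, skewness, amplitude entropy, and the
   spectral centroid.
4. **Classification.** Either three per-class diagonal-covariance
   Gaussian mixtures (cough/snore/noise) scored by
   `LLR = log(S1 / max(S2, S3))`, or a small fully connected network
   (two 100-unit ReLU layers, 50% dropout between them, softmax over
   cough/non-cough) scored by `LLR = log(S1/S2)`. Events above an LLR
   threshold are called coughs.
5. **Sleep analysis.** Detected coughs are assigned to the 30-s hypnogram
   epoch containing their onset; counts are normalised by per-stage
   duration into coughs/hour, compared across stages with Wilcoxon
   rank-sum tests, correlated with subject covariates (Pearson,
   Spearman, partial), and tabulated into post-cough stage transitions.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| frame length / overlap | 20 ms / 50% | energy analysis resolution |
| `B` | 0.08 | histogram count fraction defining the background tail |
| `A` | 100 | gap between the noise tail and the trigger threshold `th1` (linear energy) |
| duration filter | 0.15–1.1 s | plausible cough lengths |
| part-1 window | 0.079 s | where the explosive peak is sought |
| voiced threshold | 0.45 | third-part decision on the 50–255 Hz score |
| GMM orders | (1, 1, 16) | cough/snore/noise component counts |
| network | 31→100→100→2 | 13,502 parameters at 31 inputs |
| training | Adam, lr 5e-6, batch 32, 250 epochs | reference recipe, class-weighted cross-entropy |
| LLR thresholds | 1.17 (GMM), −2.22 (network) | reference operating points; the pipeline can instead pick the J-optimal threshold on a development split |

`A` deserves a note. The trigger threshold is `th1 = A *` (the energy at
which the histogram's right tail first falls below `B` times the modal
count — i.e. where the background peak ends). The onset/offset thresholds
are fixed fractions of `th1`, floored at the modal (background) energy.
If `A` is small, those floors bind, and since roughly half of all
background frames lie above the modal energy, the onset/offset scans walk
randomly into the background and boundaries smear by tens of
milliseconds. `A` is explicitly a constant to be calibrated on training
data; calibrating on the synthetic training split gives `A = 100`
(+20 dB), which keeps `th1` well below every event peak while placing
`0.01*th1` just above the background bulk. Boundary errors then stay
within ±2 frame hops for >95% of planted events. Users adapting the
detector to other recording chains should expect to re-calibrate `A`
(and should check `th1` sits between the background mode and the event
peaks, which `compute_thresholds()` enforces).

Two smaller reading choices: the energy histogram is built on dB energy
(100 bins over the recording's dynamic range), and `argmax{E_hist}` is
taken to mean the modal bin's *energy value* (the background level), not
its index. Both are configurable.

## The synthetic world

No recordings ship with the package; every test runs on the bundled
generator (`generate_night()`), which emulates exactly the structure the
detector assumes:

* **Coughs** (0.25–0.9 s): a broadband burst with ~1.5 ms attack and fast
  decay (phase 1), turbulence 6–14 dB below it with a slow decay
  (phase 2), and — for 2 of 5 coughs — a harmonic tail at a fundamental
  drawn from 100–220 Hz (phase 3). The duration range leaves margin
  inside the 0.15–1.1 s detector filter so boundary slop cannot push
  detected durations outside it.
* **Snores** (0.2–1.0 s): an 8-harmonic stack at 20–80 Hz under
  breathing-cycle amplitude modulation.
* **Noises** (0.2–0.8 s): broadband, band-passed, or low-frequency
  rumble bursts.
* **Background**: pink noise 40 dB below the mean event peak,
  high-passed at 40 Hz. Without that high-pass the sub-40 Hz components
  modulate 20 ms frame energies so strongly that the background loses
  the sharp histogram mode the thresholding relies on; a real recording
  chain's low-frequency roll-off has the same effect.
* **Hypnogram**: a fixed 5-state Markov chain over 30-s epochs whose
  stationary distribution is dominated by N2 (~42%), with sticky Wake
  and N3. It is a plausible default, not fitted to clinical data.

Event onsets are Poisson per class with rejection of overlaps (minimum
gap 0.25 s); amplitudes are drawn from 0.3–0.7 full scale. The paper
trail behind the defaults: no public SNR or amplitude statistics exist
for the original private corpus, so these values were chosen once for
detectability and kept.

**What a green test establishes — and what it does not.** The synthetic
classes are, by construction, acoustically well separated: the end-to-end
suite demonstrates that the machinery (detection, segmentation, features,
training, thresholding, evaluation) is correct and that the advertised
operating points are reachable on data with the assumed structure. It
does not demonstrate clinical performance: real nights have overlapping
events, non-stationary backgrounds, within-class acoustic diversity and
label noise that the generator deliberately omits (reverberation and
physiological fidelity are out of scope).

## Numerical choices

* Voiced scores use mean-removed, length-unbiased normalised
  autocorrelation, maximised over the lag band; windows are 64 ms
  (50–255 Hz) and 128 ms (10–100 Hz) on a 10 ms grid, because a 20 ms
  frame cannot hold one 10–100 Hz period. Event-level `voiced_H`/
  `voiced_L` are the framewise maxima.
* MFCCs: 26 triangular mel filters over 0–8 kHz, 512-point FFT, DCT-II,
  c1–c12 kept (c0 is redundant with the energy features), averaged per
  part. The second part spans from the second-part onset to the voiced
  onset when present, else to the event end.
* LPC: order 8 by the autocorrelation method (Levinson-Durbin) on
  Hamming-windowed 20 ms frames; silent/unstable frames contribute zero
  coefficients.
* Entropy: 100 equal-width amplitude bins between the event's min and
  max, `0*log2(0) := 0`; a constant event has zero entropy.
* Spectral centroid: power-spectrum weighting (`|X|^2`). With raw
  magnitude weighting, Hamming-window leakage drags a pure 1 kHz tone's
  centroid to ~1035 Hz; with power weighting it sits at 1000.0 Hz.
* Kurtosis is the raw standardised fourth moment (not excess); both
  moment features return 0 for degenerate (constant) events.
* GMM: diagonal covariances with a 1e-6 variance floor on z-scored
  features (training statistics stored with the model), k-means
  initialisation with 5 seeded restarts, 200 EM iterations, tolerance
  1e-6. The covariance determinant in the mixture density is per
  component (the source prints it without a subscript; any other reading
  makes the mixture improper).
* Network: Glorot-uniform initialisation, inverse-frequency class
  weights `n/(2*n_class)`, no early stopping, probabilities clipped at
  1e-12 before the LLR. Training is bit-reproducible for a fixed seed
  on one CPU.
* Degenerate events: a missing interior energy minimum makes the second
  part start right after the peak frame (flagged); an empty second part
  makes the energy ratio fall back to the global post-onset peak.
* Ties in threshold sweeps are grouped (one operating point per distinct
  score), which makes the trapezoidal ROC-AUC equal the Mann-Whitney
  statistic exactly.

## Design choices where the design was open

* SFS runs to `max_features` and returns the subset at the criterion
  maximum, rather than stopping early; the inner classifier keeps the
  final orders (1, 1, 16) for tractability, and the operating threshold
  inside the wrapper is the development-optimal one.
* Whether the event-level voiced feature is the max or mean over frames
  is unspecified in the source; max is used (it matches the third-part
  detection rule).
* Stage assignment uses the epoch containing the event onset, epochs
  half-open `[t, t+30)`.
* 5-fold cross-validation reuses a fixed feature mask rather than
  re-running SFS per fold.
* p-values are reported raw (no multiple-testing correction), matching
  the analysis being reproduced.

## Limitations

Overlapping events are not separated; detection is offline (whole-night
histogram), not streaming; the generator makes no claim of physiological
cough acoustics; and the published headline numbers (86.1% sensitivity,
99.9% specificity on an 89-subject private test set) cannot be reproduced
here because those recordings are not deposited — the package reproduces
the *method* and its in-paper-derivable quantities (network parameter
count, metric reconstructions from the printed confusion tables) exactly,
and demonstrates the pipeline's operating behaviour on the synthetic
world.
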