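# noctcough

Detection and sleep-stage analysis of nocturnal cough sounds from
non-contact microphone recordings.

Coughing at night is clinically informative — for respiratory disease
tracking, medication response, and the interaction between cough and
sleep — but manual annotation of whole-night audio is impractical and
contact sensors disturb the very sleep under study. `noctcough`
implements an automatic pipeline for whole-night recordings:

1. **Pre-processing** — DC removal, anti-aliased down-sampling to 16 kHz.
2. **Event detection** — short-time frame energy
   *E(j) = Σᵢ x(i)²* (20 ms frames, 50% overlap) thresholded by three
   recording-adaptive levels read off the energy histogram:
   *th₁ = A·E*<sub>tail</sub> triggers an event,
   *th₂ = max(0.15·th₁, E*<sub>mode</sub>*)* locates its onset and
   *th₃ = max(0.01·th₁, E*<sub>mode</sub>*)* its offset (hysteresis),
   followed by a 0.15–1.1 s duration filter.
3. **Features** — each event is split into the cough phases (explosive /
   turbulent / optional voiced tail) and summarised by 34 features:
   energy-peak index, 12+12 MFCCs (first/second part), voiced
   autocorrelation scores in 50–255 Hz and 10–100 Hz, cross-frame LPC
   variance, part-1/part-2 energy ratio, mean ZCR, kurtosis, skewness,
   amplitude entropy, spectral centroid.
4. **Classification** — per-class Gaussian mixtures (cough/snore/noise)
   fused by *LLR = log(S₁ / max(S₂, S₃))*, and/or a 31→100→100→2
   fully connected softmax network (13,502 parameters, 50% dropout,
   class-weighted cross-entropy, Adam at 5·10⁻⁶) scored by
   *LLR = log(S₁/S₂)*; sequential forward feature selection with
   criterion *J = (sensitivity + PPV)/2*; threshold selection, ROC/PR
   curves, Cohen's kappa, subject-wise k-fold cross-validation.
5. **Sleep analysis** — coughs are aligned to a 30-s-epoch hypnogram,
   normalised into per-stage coughs/hour, compared with Wilcoxon
   rank-sum tests, correlated (Pearson/Spearman/partial) with subject
   covariates, and tabulated into post-cough stage transitions.

A seeded synthetic nocturnal-audio generator (annotated WAV + CSV + TSV
hypnogram) makes the whole pipeline testable without clinical data; see
the methods vignette (`vignettes/nocturnal-cough-detection.Rmd`) for the
model, the generator's assumptions, and every numerical choice.

## Worked example

```r
library(noctcough)
set.seed(7)
cfg <- synth_config(night_duration = 600,
                    events_per_hour = c(cough = 60, snore = 300, noise = 300))
night  <- generate_night(cfg)                       # annotated audio + hypnogram
rec    <- recording(night$samples, night$sample_rate, subject_id = "demo")
events <- detect_recording(rec)                     # adaptive-threshold detector
labels <- match_events(events, night$annotations)$label
table(labels)
feats  <- extract_feature_matrix(events, rec$sample_rate)  # 34 columns
rates  <- cough_rate_by_stage(events$start_s[labels == "cough"],
                              night$hypnogram)
rates
```

prints

```
labels
cough noise snore
   11    52    47

  stage count duration_h     rate
1     W     0 0.01666667  0.00000
2   REM     0 0.00000000       NA
3    N1     3 0.04166667 72.00000
4    N2     8 0.10833333 73.84615
5    N3     0 0.00000000       NA
```

All 110 planted events were recovered (110 detected). Counts are
events, `duration_h` the time this short demo night spent in each stage,
and `rate` the duration-normalised cough rate; stages never visited get
an undefined (`NA`) rate rather than 0. On a full-length corpus the same
calls feed `train_gmm_system()` / `train_dnn()`, `gmm_llr()` /
`dnn_llr()` and `metrics_from_confusion()` — `run_pipeline()` wires the
whole chain together from one config, and `inst/cli/noctcough` exposes
`synth` / `detect` / `analyze` / `run-all` verbs on the command line.

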