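#' Configuration for the synthetic nocturnal-audio generator
#'
#' The generator emulates the acoustic structure the detector assumes:
#' transient cough events with an explosive first phase, a lower-amplitude
#' turbulent second phase and an optional voiced (harmonic) third phase;
#' semi-periodic amplitude-modulated snores; broadband transient noises; a
#' stationary pink-noise background; and a 5-stage hypnogram. About 2 in 5
#' coughs carry the voiced tail.
#'
#' @param sample_rate output rate in Hz
#' @param night_duration recording length in seconds
#' @param events_per_hour named rates (events/h) for `cough`, `snore`, `noise`
#' @param voiced_cough_fraction probability a cough has a voiced third phase
#' @param cough_duration_range cough duration bounds in seconds (kept inside
#'   the detector's 0.15–1.1 s filter with margin for boundary slop)
#' @param snore_duration_range,noise_duration_range duration bounds (s)
#' @param snore_f0_range snore fundamental range, inside \[10, 100\] Hz
#' @param voiced_f0_range voiced-tail fundamental range, inside \[50, 255\] Hz
#' @param event_to_background_snr peak-event-to-background level in dB
#' @param event_peak_range peak amplitude range of events (full scale = 1)
#' @param min_gap minimum silence between consecutive events (s)
#' @param cough_stage_multiplier optional named per-stage multiplier of the
#'   cough rate (names among `r paste(STAGES, collapse = ", ")`); `NULL`
#'   places coughs homogeneously
#' @return a `SynthConfig` list
#' @export
synth_config <- function(sample_rate = 16000,
                         night_duration = 600,
                         events_per_hour = c(cough = 30, snore = 60,
                                             noise = 60),
                         voiced_cough_fraction = 2 / 5,
                         cough_duration_range = c(0.25, 0.9),
                         snore_duration_range = c(0.2, 1.0),
                         noise_duration_range = c(0.2, 0.8),
                         snore_f0_range = c(20, 80),
                         voiced_f0_range = c(100, 220),
                         event_to_background_snr = 40,
                         event_peak_range = c(0.3, 0.7),
                         min_gap = 0.25,
                         cough_stage_multiplier = NULL) {
  cfg <- list(sample_rate = sample_rate, night_duration = night_duration,
              events_per_hour = events_per_hour,
              voiced_cough_fraction = voiced_cough_fraction,
              cough_duration_range = cough_duration_range,
              snore_duration_range = snore_duration_range,
              noise_duration_range = noise_duration_range,
              snore_f0_range = snore_f0_range,
              voiced_f0_range = voiced_f0_range,
              event_to_background_snr = event_to_background_snr,
              event_peak_range = event_peak_range,
              min_gap = min_gap,
              cough_stage_multiplier = cough_stage_multiplier)
  stopifnot(all(events_per_hour >= 0),
            voiced_cough_fraction >= 0, voiced_cough_fraction <= 1,
            cough_duration_range[1] > 0,
            cough_duration_range[2] < night_duration,
            snore_f0_range[1] >= 10, snore_f0_range[2] <= 100,
            voiced_f0_range[1] >= 50, voiced_f0_range[2] <= 255)
  structure(cfg, class = "SynthConfig")
}

# pink (1/f amplitude) noise via spectral shaping, unit RMS. Content below
# `highpass_hz` is removed, mimicking a recording chain's low-frequency
# roll-off; without it the sub-40 Hz components modulate the 20 ms frame
# energy so strongly that the background loses its sharp histogram mode.
.pink_noise <- function(n, fs = 16000, highpass_hz = 40) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- fft(rnorm(m))
  f <- c(1, seq_len(m - 1))                 # avoid the DC singularity
  f <- pmin(f, m - f + 1)                   # mirror for negative frequencies
  X <- X / sqrt(f)
  X[f * fs / m < highpass_hz] <- 0
  x <- Re(fft(X, inverse = TRUE))[seq_len(n)]
  x / sqrt(mean(x^2))
}

# smooth attack/decay envelope helpers
.env_attack_decay <- function(n, n_attack, tau) {
  i <- seq_len(n)
  att <- pmin(1, (i - 1) / max(1, n_attack))
  dec <- exp(-pmax(0, i - n_attack) / tau)
  att * dec
}

.synth_cough <- function(dur, voiced, f0, fs) {
  n <- round(dur * fs)
  l1 <- round(runif(1, 0.03, 0.08) * fs)          # explosive phase
  l1 <- min(l1, n - round(0.1 * fs))
  x <- numeric(n)
  # phase 1: broadband burst, ~1.5 ms attack, fast decay
  x[1:l1] <- rnorm(l1) * .env_attack_decay(l1, round(0.0015 * fs), l1 / 2.5)
  # short dip so the first local energy minimum is well defined
  gap <- round(0.01 * fs)
  p2_start <- min(n, l1 + gap)
  a2 <- 10^(-runif(1, 6, 14) / 20)                 # 6–14 dB below phase 1
  v_start <- if (voiced) max(p2_start + 1, n - round(0.4 * n)) else n + 1
  if (p2_start < v_start) {
    idx <- p2_start:min(n, v_start - 1)
    m <- length(idx)
    env <- a2 * pmax(exp(-2.3 * (seq_len(m) - 1) / max(1, m)), 0.25) *
      pmin(1, seq_len(m) / max(1, gap))
    x[idx] <- rnorm(m) * env
  }
  if (voiced && v_start <= n) {
    idx <- v_start:n
    m <- length(idx)
    t <- (seq_len(m) - 1) / fs
    # glottal-pulse-like harmonic stack plus residual turbulence
    h <- seq_len(6)
    tail <- colSums(matrix(sin(2 * pi * outer(h * f0, t) +
                               runif(6, 0, 2 * pi)) / h, nrow = 6))
    tail <- tail / max(abs(tail))
    env <- a2 * pmax(exp(-2.3 * (seq_len(m) - 1) / max(1, m)), 0.25)
    x[idx] <- env * (0.9 * tail + 0.1 * rnorm(m))
  }
  # 15 ms release so the waveform reaches the noise floor at the
  # annotated offset instead of trailing past it
  x <- x * pmin(1, rev(seq_len(n)) / round(0.015 * fs))
  x / max(abs(x))
}

.synth_snore <- function(dur, f0, fs) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  h <- seq_len(8)
  w <- colSums(matrix(sin(2 * pi * outer(h * f0, t) +
                          runif(8, 0, 2 * pi)) / h, nrow = 8))
  # breathing-cycle amplitude modulation under a trapezoid gate (30 ms
  # attack, 50 ms release: soft enough to sound snore-like, sharp enough
  # that the energy detector sees the annotated boundaries)
  am <- 1 + 0.3 * sin(2 * pi * runif(1, 2, 5) * t + runif(1, 0, 2 * pi))
  gate <- pmin(1, seq_len(n) / round(0.02 * fs),
               rev(seq_len(n)) / round(0.025 * fs))
  x <- w * am * gate + 0.02 * rnorm(n)
  x / max(abs(x))
}

.synth_noise <- function(dur, fs) {
  n <- round(dur * fs)
  kind <- sample(c("broadband", "bandpassed", "rumble"), 1)
  x <- rnorm(n)
  if (kind != "broadband") {
    lim <- if (kind == "bandpassed") {
      fc <- exp(runif(1, log(300), log(5000)))
      c(fc / 1.5, fc * 1.5)
    } else c(30, 150)
    m <- stats::nextn(n, c(2, 3, 5))
    X <- fft(c(x, numeric(m - n)))
    f <- (seq_len(m) - 1) * fs / m
    f <- pmin(f, fs - f)
    X[f < lim[1] | f > lim[2]] <- 0
    x <- Re(fft(X, inverse = TRUE))[seq_len(n)] / m
  }
  gate <- pmin(1, seq_len(n) / round(0.015 * fs)) *
    pmin(1, rev(seq_len(n)) / round(0.025 * fs))
  x <- x * gate
  x / max(abs(x))
}

#' Generate one synthetic sound event
#'
#' Draws duration and (where relevant) fundamental frequency from the
#' configured ranges and synthesises a normalised waveform: coughs get a
#' sharp-attack broadband burst, a 6–14 dB weaker turbulent phase and,
#' if `voiced`, a harmonic tail; snores are amplitude-modulated harmonic
#' stacks at a low fundamental; noises are flat, band-passed or rumbling
#' broadband bursts.
#'
#' @param kind one of `"cough"`, `"snore"`, `"noise"`
#' @param voiced for coughs: include the voiced third phase?
#' @param config a [synth_config()]
#' @param scale peak amplitude multiplier (0 gives an all-zero waveform)
#' @return numeric waveform with peak amplitude `<= scale`
#' @export
generate_event <- function(kind = c("cough", "snore", "noise"),
                           voiced = FALSE, config = synth_config(),
                           scale = 1) {
  kind <- match.arg(kind)
  fs <- config$sample_rate
  x <- switch(kind,
    cough = .synth_cough(runif(1, config$cough_duration_range[1],
                               config$cough_duration_range[2]),
                         voiced,
                         runif(1, config$voiced_f0_range[1],
                               config$voiced_f0_range[2]), fs),
    snore = .synth_snore(runif(1, config$snore_duration_range[1],
                               config$snore_duration_range[2]),
                         runif(1, config$snore_f0_range[1],
                               config$snore_f0_range[2]), fs),
    noise = .synth_noise(runif(1, config$noise_duration_range[1],
                               config$noise_duration_range[2]), fs))
  x * scale
}

#' Default sleep-stage transition matrix (30-s epochs)
#'
#' A fixed, plausible 5-state Markov chain over Wake/REM/N1/N2/N3 whose
#' stationary distribution is dominated by N2 (light sleep occupies roughly
#' half the night), with sticky Wake and N3 runs. Not fitted to any
#' clinical dataset.
#'
#' @return 5x5 row-stochastic matrix with dimnames `W, REM, N1, N2, N3`
#' @export
default_sleep_transition <- function() {
  P <- rbind(
    W   = c(W = .88, REM = .01, N1 = .10, N2 = .01, N3 = 0),
    REM = c(.05, .85, .05, .05, 0),
    N1  = c(.05, .02, .60, .33, 0),
    N2  = c(.02, .04, .03, .85, .06),
    N3  = c(.01, 0,   0,   .14, .85))
  colnames(P) <- STAGES[c(1, 2, 3, 4, 5)]
  rownames(P) <- colnames(P)
  P
}

#' Generate a synthetic hypnogram
#'
#' One stage label per 30-s epoch, sampled from a 5-state Markov chain.
#'
#' @param night_duration duration in seconds (>= 30)
#' @param transition row-stochastic 5x5 transition matrix (rows/cols in the
#'   order `W, REM, N1, N2, N3`)
#' @param start initial stage
#' @param epoch_length epoch length in seconds (30 by convention)
#' @return a `Hypnogram`: list with `stages` (character vector),
#'   `epoch_length` and `start_time`
#' @export
generate_hypnogram <- function(night_duration,
                               transition = default_sleep_transition(),
                               start = "W", epoch_length = 30) {
  if (night_duration < epoch_length)
    stop("night_duration must cover at least one ", epoch_length, "-s epoch")
  if (is.null(dimnames(transition)))
    dimnames(transition) <- list(STAGES, STAGES)
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-8), start %in% STAGES)
  n <- floor(night_duration / epoch_length)
  stages <- character(n)
  s <- start
  for (i in seq_len(n)) {
    stages[i] <- s
    s <- sample(STAGES, 1, prob = transition[s, STAGES])
  }
  hypnogram(stages, epoch_length = epoch_length)
}

# Draw event onsets/durations without synthesising audio. Rejection
# sampling keeps events separated by at least min_gap; after `retries`
# failed draws for an event the night is declared too dense.
.plan_class <- function(n_events, durations, night_duration, placed,
                        min_gap, retries = 100) {
  onsets <- numeric(0)
  for (i in seq_len(n_events)) {
    ok <- FALSE
    for (r in seq_len(retries)) {
      on <- runif(1, min_gap, night_duration - durations[i] - min_gap)
      off <- on + durations[i]
      clash <- any(on < placed$offset + min_gap &
                   off > placed$onset - min_gap)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("event density incompatible with non-overlapping placement")
    placed <- rbind(placed, data.frame(onset = on, offset = off))
    onsets[i] <- on
  }
  list(onsets = onsets, placed = placed)
}

#' Plan the ground-truth event annotations of a synthetic night
#'
#' Draws per-class Poisson event counts, durations, voiced flags and
#' non-overlapping onsets — everything except the audio itself. Used by
#' [generate_night()] and directly testable (e.g. Poisson count checks)
#' without the cost of waveform synthesis.
#'
#' @param config a [synth_config()]
#' @param hyp optional `Hypnogram`; required when
#'   `config$cough_stage_multiplier` is set, in which case cough counts are
#'   drawn per epoch at the stage-modulated rate
#' @return data.frame with `onset_s`, `offset_s`, `label`, `voiced`, sorted
#'   by onset
#' @export
plan_night_events <- function(config, hyp = NULL) {
  hours <- config$night_duration / 3600
  placed <- data.frame(onset = numeric(0), offset = numeric(0))
  rows <- list()
  for (cls in c("cough", "snore", "noise")) {
    rate <- config$events_per_hour[[cls]]
    rng <- config[[paste0(cls, "_duration_range")]]
    if (cls == "cough" && !is.null(config$cough_stage_multiplier)) {
      if (is.null(hyp)) stop("stage-modulated cough rates need a hypnogram")
      mult <- config$cough_stage_multiplier
      ep_h <- hyp$epoch_length / 3600
      onsets <- numeric(0)
      for (e in seq_along(hyp$stages)) {
        lam <- rate * (mult[[hyp$stages[e]]] %||% 1) * ep_h
        k <- rpois(1, lam)
        if (k > 0)
          onsets <- c(onsets, hyp$start_time + (e - 1) * hyp$epoch_length +
                        runif(k, 0, hyp$epoch_length))
      }
      onsets <- onsets[onsets < config$night_duration - rng[2] - config$min_gap]
      n <- length(onsets)
      durs <- runif(n, rng[1], rng[2])
      keep <- logical(n)
      for (i in order(onsets)) {
        off <- onsets[i] + durs[i]
        clash <- any(onsets[i] < placed$offset + config$min_gap &
                     off > placed$onset - config$min_gap)
        if (!clash) {
          keep[i] <- TRUE
          placed <- rbind(placed, data.frame(onset = onsets[i], offset = off))
        }
      }
      onsets <- onsets[keep]; durs <- durs[keep]; n <- length(onsets)
    } else {
      n <- rpois(1, rate * hours)
      durs <- runif(n, rng[1], rng[2])
      pl <- .plan_class(n, durs, config$night_duration, placed,
                        config$min_gap)
      onsets <- pl$onsets; placed <- pl$placed
    }
    if (n > 0)
      rows[[cls]] <- data.frame(
        onset_s = onsets, offset_s = onsets + durs, label = cls,
        voiced = if (cls == "cough")
          runif(n) < config$voiced_cough_fraction else FALSE)
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               label = character(0), voiced = logical(0))
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete annotated synthetic night
#'
#' Pink-noise background plus non-overlapping cough/snore/noise events at
#' the configured per-hour rates, with exact annotations and a Markov-chain
#' hypnogram. Fully reproducible given `set.seed()`.
#'
#' @param config a [synth_config()]
#' @param hypnogram optional pre-built `Hypnogram` (generated when `NULL`
#'   and the night spans at least one epoch)
#' @return a `SyntheticNight`: list with `samples`, `sample_rate`,
#'   `annotations` (data.frame) and `hypnogram`
#' @export
generate_night <- function(config = synth_config(), hypnogram = NULL) {
  fs <- config$sample_rate
  n <- round(config$night_duration * fs)
  if (is.null(hypnogram) && config$night_duration >= 30)
    hypnogram <- generate_hypnogram(config$night_duration)
  ann <- plan_night_events(config, hyp = hypnogram)
  peak_ref <- mean(config$event_peak_range)
  bg_rms <- peak_ref * 10^(-config$event_to_background_snr / 20)
  x <- .pink_noise(n, fs) * bg_rms
  for (i in seq_len(nrow(ann))) {
    dur <- ann$offset_s[i] - ann$onset_s[i]
    f0 <- switch(ann$label[i],
      cough = runif(1, config$voiced_f0_range[1], config$voiced_f0_range[2]),
      snore = runif(1, config$snore_f0_range[1], config$snore_f0_range[2]),
      0)
    w <- switch(ann$label[i],
      cough = .synth_cough(dur, ann$voiced[i], f0, fs),
      snore = .synth_snore(dur, f0, fs),
      noise = .synth_noise(dur, fs))
    peak <- runif(1, config$event_peak_range[1], config$event_peak_range[2])
    i0 <- round(ann$onset_s[i] * fs)
    idx <- (i0 + 1):min(n, i0 + length(w))
    x[idx] <- x[idx] + w[seq_along(idx)] * peak
  }
  x <- pmin(1, pmax(-1, x))
  structure(list(samples = x, sample_rate = fs, annotations = ann,
                 hypnogram = hypnogram, config = config),
            class = "SyntheticNight")
}

#' Write a synthetic night to disk
#'
#' Writes `night.wav` (PCM 16-bit), `annotations.csv`
#' (`onset_s, offset_s, label, voiced`) and `hypnogram.tsv`
#' (`epoch_index, stage`) into `dir`.
#'
#' @param night a `SyntheticNight`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_night <- function(night, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wav(night$samples, file.path(dir, "night.wav"), night$sample_rate)
  write.csv(night$annotations, file.path(dir, "annotations.csv"),
            row.names = FALSE)
  if (!is.null(night$hypnogram))
    write_hypnogram_tsv(night$hypnogram, file.path(dir, "hypnogram.tsv"))
  invisible(dir)
}
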