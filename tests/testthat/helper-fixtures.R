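# shared fixture builders; everything is generated in code at test time

fixture_tone <- function(freq, fs = 16000, dur = 1, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs)
}

# a small, dense synthetic night for detector/feature tests
fixture_night_config <- function(duration = 300) {
  synth_config(night_duration = duration,
               events_per_hour = c(cough = 150, snore = 600, noise = 600))
}

# synthesise n isolated events of one class (waveforms only)
fixture_events <- function(n, kind, voiced = FALSE,
                           config = synth_config(), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    generate_event(kind, voiced = voiced, config = config))
}

# independent textbook kappa: po/pe from the 2x2 table
oracle_kappa <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  (po - pe) / (1 - pe)
}

expect_rel_equal <- function(object, expected, tol = 1e-10) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-300), tol)
}
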