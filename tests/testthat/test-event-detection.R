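test_that("frame energy matches the direct definition", {
  fs <- 16000
  ones <- recording(rep(1, fs), fs)
  es <- frame_energy(ones)
  expect_true(all(es$E == 320))
  expect_length(es$E, (fs - 320) %/% 160 + 1)
  expect_true(all(frame_energy(recording(numeric(fs), fs))$E == 0))
  # random signal vs brute-force loop oracle
  set.seed(2)
  x <- rnorm(5000)
  es2 <- frame_energy(recording(x, fs))
  brute <- vapply(seq_along(es2$E), function(j) {
    i0 <- (j - 1) * es2$hop
    sum(x[(i0 + 1):(i0 + es2$n_frame)]^2)
  }, numeric(1))
  expect_lt(max(abs(es2$E - brute)), 1e-9)
  # non-divisible hop takes the direct path
  es3 <- frame_energy(recording(x, fs), frame_length = 0.02, overlap = 0.3)
  brute3 <- vapply(seq_along(es3$E), function(j) {
    i0 <- (j - 1) * es3$hop
    sum(x[(i0 + 1):(i0 + es3$n_frame)]^2)
  }, numeric(1))
  expect_lt(max(abs(es3$E - brute3)), 1e-9)
  expect_error(frame_energy(recording(rnorm(10), fs)), "shorter")
})

test_that("energy histogram conserves counts and finds the mode", {
  fs <- 16000
  # constant energy collapses to a single bin
  es <- frame_energy(recording(rep(0.5, fs), fs))
  h <- build_histogram(es)
  expect_identical(sum(h$counts > 0), 1L)
  # two-level series: modal bin at the 90% low level
  x <- c(rep(0.01, 9 * fs), rep(1, fs))
  h2 <- build_histogram(frame_energy(recording(x, fs)))
  low_db <- 10 * log10(320 * 0.01^2)
  expect_lt(abs(h2$mids_db[h2$modal_bin] - low_db), 1)
  # count conservation on random input
  set.seed(3)
  es3 <- frame_energy(recording(rnorm(fs), fs))
  h3 <- build_histogram(es3)
  expect_identical(sum(h3$counts), length(es3$E))
})

test_that("thresholds obey the floors, ordering and failure modes", {
  fs <- 16000
  set.seed(4)
  # background at amplitude 0.01 with occasional loud events
  x <- rnorm(60 * fs) * 0.01
  ev_at <- seq(fs, length(x) - fs, by = 5 * fs)
  for (i in ev_at) x[i:(i + 3200)] <- rnorm(3201) * 0.5
  es <- frame_energy(recording(x, fs))
  h <- build_histogram(es)
  th <- compute_thresholds(h, A = 100)
  expect_true(th$th3 <= th$th2 && th$th2 <= th$th1)
  # th2/th3 floors: small A drives both ratios below the modal energy
  th_small <- compute_thresholds(h, A = 1.01)
  modal_E <- 10^(th_small$modal_db / 10)
  expect_equal(th_small$th2, modal_E)
  expect_equal(th_small$th3, modal_E)
  # A too small to clear the background mode errors
  expect_error(compute_thresholds(h, A = 0.2), "modal background")
  # separation: background frames below th2, event peaks above th1
  ev_frames <- unique(unlist(lapply(ev_at, function(i)
    floor((i + 1000) / es$hop) + 1)))
  bg_frames <- setdiff(seq_along(es$E),
                       unlist(lapply(ev_at, function(i)
                         (floor(i / es$hop) - 2):(floor((i + 3200) / es$hop) + 2))))
  expect_true(all(es$E[ev_frames] > th$th1))
  expect_gt(mean(es$E[bg_frames] < th$th2), 0.99)
})

test_that("detect_events applies hysteresis and the duration filter", {
  fs <- 16000
  th <- structure(list(th1 = 10, th2 = 1, th3 = 0.5, A = 100, B = 0.08),
                  class = "EnergyThresholds")
  mk_es <- function(E) structure(
    list(E = E, frame_length = 0.02, overlap = 0.5, n_frame = 320,
         hop = 160, sample_rate = fs), class = "EnergySeries")
  # constant sub-th1 energy: nothing
  expect_identical(nrow(detect_events(mk_es(rep(5, 100)), th)), 0L)
  # single 0.5-s rectangular burst: one event within one hop of truth
  E <- rep(0.1, 300); E[101:150] <- 100        # frames 101..150 = 0.5 s
  ev <- detect_events(mk_es(E), th)
  expect_identical(nrow(ev), 1L)
  expect_lte(abs(ev$start_sample - 100 * 160), 160)
  expect_lte(abs(ev$end_sample - (150 * 160 + 160)), 320)
  # 0.05-s burst is dropped by the duration filter
  E2 <- rep(0.1, 300); E2[101:105] <- 100
  expect_identical(nrow(detect_events(mk_es(E2), th)), 0L)
  # events never overlap; count bounded by up-crossings
  set.seed(5)
  E3 <- runif(2000, 0, 30)
  ev3 <- detect_events(mk_es(E3), th)
  if (nrow(ev3) > 1)
    expect_true(all(ev3$start_sample[-1] >= head(ev3$end_sample, -1)))
  ups <- sum(diff(E3 >= th$th1) == 1) + (E3[1] >= th$th1)
  expect_lte(nrow(ev3), ups)
})

test_that("detector recovers planted events with accurate boundaries", {
  set.seed(21)
  night <- generate_night(fixture_night_config(300))
  rec <- recording(night$samples, night$sample_rate)
  ev <- detect_recording(rec)
  ann <- night$annotations
  hit <- vapply(seq_len(nrow(ann)), function(i)
    any(ev$start_s < ann$offset_s[i] & ev$end_s > ann$onset_s[i]),
    logical(1))
  expect_gte(mean(hit), 0.95)
  m <- match_events(ev, ann)
  berr <- pmax(abs(ev$start_s - ann$onset_s[m$matched]),
               abs(ev$end_s - ann$offset_s[m$matched]))
  expect_gte(mean(berr <= 2 * 0.010 + 1e-9), 0.95)

  # scale covariance: doubling the waveform scales E and thresholds by 4
  # and leaves detected boundaries unchanged
  es1 <- frame_energy(rec)
  rec2 <- recording(2 * night$samples, night$sample_rate)
  es2 <- frame_energy(rec2)
  expect_lt(max(abs(es2$E - 4 * es1$E) / (4 * es1$E + 1e-12)), 1e-9)
  ev2 <- detect_recording(rec2)
  expect_equal(ev2$start_sample, ev$start_sample)
  expect_equal(ev2$end_sample, ev$end_sample)
})
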