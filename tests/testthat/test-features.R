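fs <- 16000

test_that("partition_event finds the part boundaries", {
  # two-level burst: 60 ms loud, quiet thereafter -> E_p in the loud
  # segment, second-part onset at the transition
  set.seed(1)
  x <- c(rnorm(960) * 0.8, rnorm(4800) * 0.05)
  p <- partition_event(x, fs)
  expect_lte(p$peak_frame, 5)                     # within the first 60 ms
  expect_gte(p$onset2, p$peak_frame + 1)
  onset2_s <- (p$onset2 - 1) * p$hop / fs
  expect_lt(abs(onset2_s - 0.06), 0.03)
  # unvoiced synthetic cough: no third part
  set.seed(2)
  w <- generate_event("cough", voiced = FALSE)
  expect_true(is.na(partition_event(w, fs)$onset3))
  # voiced synthetic cough: third part found near the true phase-3 start
  found <- 0; err_ok <- 0; n_try <- 15
  for (i in seq_len(n_try)) {
    set.seed(100 + i)
    wv <- generate_event("cough", voiced = TRUE)
    pv <- partition_event(wv, fs)
    if (!is.na(pv$onset3)) {
      found <- found + 1
      true_start <- length(wv) - round(0.4 * length(wv))   # generator law
      onset3_sample <- (pv$onset3 - 1) * pv$hop
      if (abs(onset3_sample - true_start) <= 4 * pv$hop)
        err_ok <- err_ok + 1
    }
  }
  expect_gte(found, n_try - 1)
  expect_gte(err_ok / max(found, 1), 0.8)
})

test_that("voiced_value scores periodicity in the right band", {
  expect_gt(voiced_value(fixture_tone(150, fs, 1024 / fs), fs, 50, 255),
            0.95)
  # white noise stays low (Monte-Carlo calibration at 64 ms frames)
  set.seed(5)
  v <- vapply(1:300, function(i) voiced_value(rnorm(1024), fs, 50, 255),
              numeric(1))
  expect_gte(mean(v < 0.3), 0.99)
  # 40 Hz pulse train: high in the low band, low in the high band
  p <- rep(0, 3200); p[seq(1, 3200, by = 400)] <- 1
  expect_gt(voiced_value(p, fs, 10, 100), 0.8)
  expect_lt(voiced_value(p[1:1024], fs, 50, 255), 0.3)
  # too-short frame errors with guidance
  expect_error(voiced_value(rnorm(100), fs, 10, 100), "longer")
})

test_that("lpc_variance implements the cross-frame variance exactly", {
  # deterministic stationary signal: essentially zero
  expect_lt(lpc_variance(fixture_tone(440, fs, 0.5), fs), 1e-3)
  # concatenating two different AR processes exceeds either alone
  set.seed(6)
  a <- as.numeric(arima.sim(list(ar = c(1.3, -0.6)), 6000))
  b <- as.numeric(arima.sim(list(ar = -0.9), 6000))
  v_ab <- lpc_variance(c(a, b), fs)
  expect_gt(v_ab, lpc_variance(a, fs))
  expect_gt(v_ab, lpc_variance(b, fs))
  # 2-frame, M = 2 toy equals brute-force arithmetic on the same LPCs
  set.seed(7)
  x <- rnorm(480)                                  # exactly 2 frames
  w <- noctcough:::.hamming(320)
  a_mat <- t(vapply(c(1, 161), function(i0) {
    seg <- x[i0:(i0 + 319)] * w
    r <- vapply(0:2, function(l)
      sum(seg[1:(320 - l)] * seg[(1 + l):320]), numeric(1))
    noctcough:::.levinson(r, 2)
  }, numeric(2)))
  manual <- mean(apply(a_mat, 2, var))
  expect_rel_equal(lpc_variance(x, fs, M = 2), manual, 1e-12)
  expect_error(lpc_variance(rnorm(300), fs), "2 frames")
})

test_that("extract_features returns the 34-feature contract", {
  set.seed(8)
  w <- generate_event("cough", voiced = TRUE)
  f <- extract_features(w, fs)
  expect_length(f, 34)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  # the 12 declared feature types are all present in the layout
  expect_identical(sum(grepl("^mfcc1_", names(f))), 12L)
  expect_identical(sum(grepl("^mfcc2_", names(f))), 12L)
  # constant nonzero event: single amplitude bin -> zero entropy, no
  # zero crossings
  fc <- extract_features(rep(0.5, 4800), fs)
  expect_identical(unname(fc["entropy"]), 0)
  expect_identical(unname(fc["zcr"]), 0)
  # pure 1 kHz tone: centroid within 25 Hz
  ft <- extract_features(fixture_tone(1000, fs, 0.3), fs)
  expect_lt(abs(ft["spectral_centroid"] - 1000), 25)
})

test_that("features are deterministic and amplitude-scale invariant", {
  set.seed(9)
  w <- generate_event("cough", voiced = TRUE)
  f1 <- extract_features(w, fs)
  expect_identical(f1, extract_features(w, fs))
  # every retained feature is scale-invariant by construction
  for (c_scale in c(0.5, 3)) {
    f2 <- extract_features(c_scale * w, fs)
    expect_lt(max(abs(f2 - f1) / (abs(f1) + 1e-8)), 1e-6)
  }
})

test_that("class-conditional voiced features separate the classes", {
  n <- 150
  cfgv <- synth_config()
  vH_cough <- vapply(seq_len(n), function(i) {
    set.seed(1000 + i)
    extract_features(generate_event("cough", voiced = TRUE), fs)["voiced_H"]
  }, numeric(1))
  vH_noise <- numeric(n); vL_noise <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(2000 + i)
    f <- extract_features(generate_event("noise"), fs)
    vH_noise[i] <- f["voiced_H"]; vL_noise[i] <- f["voiced_L"]
  }
  vL_snore <- vapply(seq_len(n), function(i) {
    set.seed(3000 + i)
    extract_features(generate_event("snore"), fs)["voiced_L"]
  }, numeric(1))
  expect_lt(rank_sum_test(vH_cough, vH_noise)$p_value, 0.01)
  expect_lt(rank_sum_test(vL_snore, vL_noise)$p_value, 0.01)
})

test_that("feature CSV round-trips with the canonical header", {
  set.seed(10)
  m <- rbind(extract_features(generate_event("cough"), fs),
             extract_features(generate_event("snore"), fs))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(m, path)
  m2 <- read_features_csv(path)
  expect_equal(unname(m2), unname(m), tolerance = 1e-12)
  expect_identical(colnames(m2), feature_names())
})
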