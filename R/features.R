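# ---- frame helpers (20 ms / 50% overlap convention, within one event) ----

.event_frame_energy <- function(x, fs, frame_length = 0.020, overlap = 0.5) {
  n_frame <- round(frame_length * fs)
  hop <- round(n_frame * (1 - overlap))
  n_frames <- max(1L, (length(x) - n_frame) %/% hop + 1L)
  E <- vapply(seq_len(n_frames), function(j) {
    i0 <- (j - 1L) * hop
    sum(x[(i0 + 1L):min(length(x), i0 + n_frame)]^2)
  }, numeric(1))
  list(E = E, n_frame = n_frame, hop = hop)
}

#' Voiced score of a frame: peak normalised autocorrelation in a pitch band
#'
#' Computes the (mean-removed, length-unbiased) normalised autocorrelation
#' and returns its maximum over the lags corresponding to
#' `[f_low, f_high]` Hz. High values indicate periodicity in that band; the
#' high band (50–255 Hz) flags vocal-cord activity in a cough's third
#' phase, the low band (10–100 Hz) flags snore periodicity.
#'
#' @param x waveform segment; must be longer than one period of `f_low`
#' @param fs sampling rate (Hz)
#' @param f_low,f_high pitch band in Hz
#' @return score in \[-1, 1\] (clamped)
#' @export
voiced_value <- function(x, fs, f_low, f_high) {
  max_lag <- ceiling(fs / f_low)
  min_lag <- max(1L, floor(fs / f_high))
  if (length(x) <= max_lag)
    stop("segment (", length(x), " samples) cannot hold one period of ",
         f_low, " Hz; use a longer analysis window")
  x <- x - mean(x)
  e0 <- sum(x^2)
  if (e0 == 0) return(0)
  n <- length(x)
  m <- stats::nextn(2L * n, c(2, 3, 5))
  X <- fft(c(x, numeric(m - n)))
  r <- Re(fft(Mod(X)^2, inverse = TRUE))[seq_len(max_lag + 1L)] / m
  lags <- min_lag:max_lag
  # unbiased normalisation so a sustained tone scores ~1 at its period
  score <- (r[lags + 1L] / (n - lags)) / (r[1L] / n)
  max(min(max(score), 1), -1)
}

# framewise voiced track every `hop_s` seconds with a `win_s` analysis
# window (a 20 ms frame cannot hold a low-pitch period, so these windows
# are wider than the energy frames). All windows of the event are
# autocorrelated in one batched FFT; columns are zero-padded, with mean
# removal and normalisation on the actual samples only, so each column
# reproduces voiced_value() on its truncated segment.
.voiced_track <- function(x, fs, f_low, f_high, win_s, hop_s = 0.010,
                          from_sample = 1L) {
  win <- round(win_s * fs)
  hop <- round(hop_s * fs)
  max_lag <- ceiling(fs / f_low)
  min_lag <- max(1L, floor(fs / f_high))
  if (from_sample > length(x))
    return(list(starts = integer(0), values = numeric(0)))
  starts <- seq(from_sample, length(x), by = hop)
  lens <- pmin(length(x) - starts + 1L, win)
  vals <- rep(NA_real_, length(starts))
  use <- lens > max_lag + 8L
  if (any(use)) {
    m <- stats::nextn(2L * win, c(2, 3, 5))
    W <- matrix(0, m, sum(use))
    ui <- which(use)
    for (j in seq_along(ui)) {
      seg <- x[starts[ui[j]]:(starts[ui[j]] + lens[ui[j]] - 1L)]
      W[seq_along(seg), j] <- seg - mean(seg)
    }
    R <- Re(stats::mvfft(Mod(stats::mvfft(W))^2, inverse = TRUE)) / m
    lags <- min_lag:max_lag
    for (j in seq_along(ui)) {
      n <- lens[ui[j]]
      r0 <- R[1L, j]
      if (r0 <= 0) { vals[ui[j]] <- 0; next }
      ok <- lags < n
      score <- (R[lags[ok] + 1L, j] / (n - lags[ok])) / (r0 / n)
      vals[ui[j]] <- max(min(max(score), 1), -1)
    }
  }
  list(starts = starts, values = vals)
}

#' Partition a sound event into its cough parts
#'
#' The peak energy `E_p` of the explosive first part is located within the
#' first 0.079 s. The second part begins at the first local minimum of the
#' frame energy after the peak. A voiced third part begins at the first
#' frame (from the second-part onset onward) whose high-band voiced score
#' exceeds 0.45, if any.
#'
#' @param x event waveform
#' @param fs sampling rate (Hz)
#' @param frame_length,overlap energy frame parameters (20 ms / 50%)
#' @param voiced_threshold third-part decision threshold on the voiced
#'   score (default 0.45)
#' @param vH_track optional precomputed full-event high-band voiced track
#'   (as returned by the internal tracker from sample 1); avoids
#'   recomputing it when the caller needs it anyway
#' @return a `CoughPartition` list: `E` (frame energies), `peak_frame`,
#'   `E_p`, `onset2`, `onset3` (frame indices, `onset3` may be `NA`),
#'   `voiced_track`, `degenerate` flag
#' @export
partition_event <- function(x, fs, frame_length = 0.020, overlap = 0.5,
                            voiced_threshold = 0.45, vH_track = NULL) {
  fe <- .event_frame_energy(x, fs, frame_length, overlap)
  E <- fe$E; hop <- fe$hop
  # frames starting inside the first 0.079 s
  first_part <- which(((seq_along(E) - 1L) * hop) / fs < 0.079)
  peak_frame <- first_part[which.max(E[first_part])]
  E_p <- E[peak_frame]
  onset2 <- NA_integer_; degenerate <- FALSE
  if (peak_frame < length(E)) {
    for (j in (peak_frame + 1L):length(E)) {
      left_ok <- E[j] <= E[j - 1L]
      right_ok <- j == length(E) || E[j] <= E[j + 1L]
      if (left_ok && right_ok && j < length(E)) { onset2 <- j; break }
    }
  }
  if (is.na(onset2)) {            # no interior local minimum: flag and fall
    onset2 <- min(peak_frame + 1L, length(E))
    degenerate <- TRUE
  }
  from2 <- (onset2 - 1L) * hop + 1L
  if (is.null(vH_track)) {
    vt <- .voiced_track(x, fs, f_low = 50, f_high = 255, win_s = 0.064,
                        from_sample = from2)
  } else {
    sel <- vH_track$starts >= from2
    vt <- list(starts = vH_track$starts[sel],
               values = vH_track$values[sel])
  }
  hit <- which(!is.na(vt$values) & vt$values > voiced_threshold)
  onset3 <- if (length(hit)) {
    onset2 + as.integer(round((vt$starts[hit[1]] - from2) / hop))
  } else NA_integer_
  structure(list(E = E, hop = hop, n_frame = fe$n_frame,
                 peak_frame = peak_frame, E_p = E_p,
                 onset2 = onset2, onset3 = onset3,
                 voiced_track = vt, degenerate = degenerate),
            class = "CoughPartition")
}

# ---- LPC ----

# Levinson-Durbin recursion on autocorrelation r[0..M]; returns the M
# prediction coefficients (sign convention: x[n] ~ sum a_k x[n-k]).
.levinson <- function(r, M) {
  a <- numeric(M)
  e <- r[1]
  if (e <= 0) return(rep(0, M))
  for (m in seq_len(M)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a[1:(m - 1)] * r[m:2])
    k <- acc / e
    a_new <- a
    a_new[m] <- k
    if (m > 1) a_new[1:(m - 1)] <- a[1:(m - 1)] - k * a[(m - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) { e <- .Machine$double.eps; }
  }
  a
}

.frame_starts <- function(n, n_frame, hop)
  seq(1L, by = hop, length.out = max(1L, (n - n_frame) %/% hop + 1L))

#' Cross-frame variance of LPC coefficients (non-stationarity measure)
#'
#' Eight linear-prediction coefficients are fitted per 20 ms Hamming frame
#' (autocorrelation method, Levinson-Durbin); the feature is the mean over
#' coefficients of their variance across the event's frames:
#' `(1/M) * sum_m (1/(K-1)) * sum_k (a_m(k) - mean_k a_m)^2`.
#' Silent or unstable frames contribute zero coefficients.
#'
#' @param x event waveform (must span at least 2 frames)
#' @param fs sampling rate (Hz)
#' @param M number of LPC coefficients (default 8)
#' @param frame_length,overlap frame parameters (20 ms / 50%)
#' @return non-negative scalar
#' @export
lpc_variance <- function(x, fs, M = 8, frame_length = 0.020, overlap = 0.5) {
  n_frame <- round(frame_length * fs)
  hop <- round(n_frame * (1 - overlap))
  starts <- .frame_starts(length(x), n_frame, hop)
  K <- length(starts)
  if (K < 2) stop("event must span at least 2 frames for LPC variance")
  w <- .hamming(n_frame)
  A <- matrix(0, nrow = K, ncol = M)
  for (k in seq_len(K)) {
    seg <- x[starts[k]:min(length(x), starts[k] + n_frame - 1L)]
    if (length(seg) < n_frame) seg <- c(seg, numeric(n_frame - length(seg)))
    seg <- seg * w
    r <- vapply(0:M, function(l)
      sum(seg[1:(n_frame - l)] * seg[(1 + l):n_frame]), numeric(1))
    A[k, ] <- .levinson(r, M)
  }
  mean(apply(A, 2, var))
}

# ---- MFCC ----

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank, rows = filters, cols = FFT bins (0..nfft/2)
.mel_bank <- function(fs, nfft, n_filters = 26, f_min = 0, f_max = fs / 2) {
  pts <- .mel_to_hz(seq(.hz_to_mel(f_min), .hz_to_mel(f_max),
                        length.out = n_filters + 2))
  bins <- 0:(nfft %/% 2) * fs / nfft
  H <- matrix(0, n_filters, length(bins))
  for (i in seq_len(n_filters)) {
    lo <- pts[i]; ce <- pts[i + 1]; hi <- pts[i + 2]
    up <- (bins - lo) / (ce - lo)
    dn <- (hi - bins) / (hi - ce)
    H[i, ] <- pmax(0, pmin(up, dn))
  }
  H
}

#' Mean mel-frequency cepstral coefficients of a segment
#'
#' 20 ms Hamming frames (50% overlap), 512-point FFT, 26 triangular mel
#' filters over 0–8 kHz, log energies, DCT-II; coefficients c1..c12 are
#' kept (c0, a pure energy term, is excluded) and averaged across frames.
#'
#' @param x waveform segment
#' @param fs sampling rate (Hz)
#' @param n_coef number of cepstral coefficients (default 12)
#' @param n_filters mel filters (default 26)
#' @return numeric vector of length `n_coef`
#' @export
mfcc_mean <- function(x, fs, n_coef = 12, n_filters = 26) {
  n_frame <- round(0.020 * fs)
  hop <- n_frame %/% 2L
  nfft <- 512L
  if (length(x) < n_frame) x <- c(x, numeric(n_frame - length(x)))
  starts <- .frame_starts(length(x), n_frame, hop)
  w <- .hamming(n_frame)
  H <- .mel_bank(fs, nfft, n_filters)
  dct <- outer(seq_len(n_coef), seq_len(n_filters) - 0.5,
               function(k, j) cos(pi * k * j / n_filters))
  cc <- matrix(0, length(starts), n_coef)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:min(length(x), starts[k] + n_frame - 1L)]
    if (length(seg) < n_frame) seg <- c(seg, numeric(n_frame - length(seg)))
    spec <- Mod(fft(c(seg * w, numeric(nfft - n_frame))))^2
    mel <- as.numeric(H %*% spec[1:(nfft %/% 2 + 1)])
    cc[k, ] <- as.numeric(dct %*% log(mel + 1e-12))
  }
  colMeans(cc)
}

# ---- the 34-dimensional feature vector ----

#' Names of the 34 acoustic features, in canonical order
#'
#' One energy index, 12 MFCCs from the first part, 12 from the second,
#' the high- and low-band voiced scores, LPC variance, the part-1/part-2
#' energy-peak ratio, mean ZCR, kurtosis, skewness, amplitude entropy and
#' the spectral centroid.
#'
#' @return character vector of length 34
#' @export
feature_names <- function() {
  c("energy_index",
    paste0("mfcc1_", 1:12), paste0("mfcc2_", 1:12),
    "voiced_H", "voiced_L", "lpc_variance", "energy_ratio", "zcr",
    "kurtosis", "skewness", "entropy", "spectral_centroid")
}

#' Extract the 34-dimensional feature vector of one sound event
#'
#' See [feature_names()] for the layout. The first/second part spans come
#' from [partition_event()]; the second part ends at the voiced-part onset
#' when one exists. The voiced scores are the maxima of the framewise
#' tracks over the whole event (64 ms windows for the 50–255 Hz band,
#' 128 ms for 10–100 Hz, 10 ms hops). Entropy uses a 100-bin amplitude
#' histogram between the event's min and max sample values, in bits. The
#' spectral centroid is computed on the magnitude spectrum of the whole
#' Hamming-windowed event.
#'
#' @param x event waveform
#' @param fs sampling rate (Hz)
#' @param part optional [partition_event()] result (recomputed when `NULL`)
#' @return named numeric vector of length 34
#' @export
extract_features <- function(x, fs, part = NULL) {
  vH <- .voiced_track(x, fs, 50, 255, win_s = 0.064)
  if (is.null(part)) part <- partition_event(x, fs, vH_track = vH)
  E <- part$E; hop <- part$hop
  n_frames <- length(E)
  onset2 <- part$onset2
  onset3 <- part$onset3
  p1_end_sample <- (onset2 - 1L) * hop
  p2_to <- if (!is.na(onset3)) onset3 - 1L else n_frames
  p2_frames <- if (onset2 <= p2_to) onset2:p2_to else integer(0)
  p2_start_sample <- (onset2 - 1L) * hop + 1L
  p2_end_sample <- min(length(x),
                       if (!is.na(onset3)) (onset3 - 1L) * hop
                       else length(x))

  # energy ratio: part-1 peak over part-2 peak; empty second part falls
  # back to the global post-onset energy peak
  if (length(p2_frames) > 0) {
    e2 <- max(E[p2_frames])
  } else {
    e2 <- if (onset2 <= n_frames) max(E[onset2:n_frames]) else min(E)
  }
  energy_ratio <- part$E_p / max(e2, .Machine$double.xmin)

  mf1 <- mfcc_mean(x[1:max(p1_end_sample, part$n_frame)], fs)
  mf2 <- mfcc_mean(x[p2_start_sample:max(p2_end_sample,
                                         p2_start_sample + 1L)], fs)

  vL <- .voiced_track(x, fs, 10, 100, win_s = 0.128)
  voiced_H <- if (all(is.na(vH$values))) 0 else max(vH$values, na.rm = TRUE)
  voiced_L <- if (all(is.na(vL$values))) 0 else max(vL$values, na.rm = TRUE)

  # mean zero-crossings per frame; sign(0) counts as positive
  starts <- .frame_starts(length(x), part$n_frame, hop)
  s <- ifelse(x >= 0, 1, -1)
  zcr <- mean(vapply(starts, function(i0) {
    seg <- s[i0:min(length(s), i0 + part$n_frame - 1L)]
    sum(seg[-1] != seg[-length(seg)])
  }, numeric(1)))

  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  kurtosis <- if (m2 > 0) mean(d^4) / m2^2 else 0
  skewness <- if (m2 > 0) mean(d^3) / m2^1.5 else 0

  rng <- range(x)
  if (diff(rng) == 0) {
    entropy <- 0
  } else {
    bi <- pmin(100L, pmax(1L, 1L + floor(100 * (x - rng[1]) / diff(rng))))
    P <- tabulate(bi, 100L) / length(x)
    P <- P[P > 0]
    entropy <- -sum(P * log2(P))
  }

  # centre of mass of the power spectrum of the whole Hamming-windowed
  # event (power rather than magnitude weighting: window leakage then
  # leaves a pure tone's centroid at the tone frequency)
  nfft <- 2^ceiling(log2(length(x)))
  w <- if (length(x) > 1) .hamming(length(x)) else 1
  X2 <- Mod(fft(c(x * w, numeric(nfft - length(x)))))^2
  half <- 1:(nfft %/% 2 + 1)
  f <- (half - 1) * fs / nfft
  spectral_centroid <- sum(f * X2[half]) / max(sum(X2[half]),
                                               .Machine$double.xmin)

  out <- c(part$peak_frame, mf1, mf2, voiced_H, voiced_L,
           lpc_variance(x, fs), energy_ratio, zcr, kurtosis, skewness,
           entropy, spectral_centroid)
  names(out) <- feature_names()
  out
}

#' Extract the feature matrix of a set of detected events
#'
#' @param events a `SoundEvents` data.frame carrying a `samples`
#'   list-column (see [detect_events()] with `rec` supplied)
#' @param fs sampling rate (Hz)
#' @return numeric matrix, one row per event, 34 named columns
#' @export
extract_feature_matrix <- function(events, fs) {
  stopifnot(!is.null(events$samples))
  out <- t(vapply(events$samples, extract_features, numeric(34), fs = fs))
  colnames(out) <- feature_names()
  out
}

#' Write / read a feature matrix as CSV with the canonical 34-column header
#'
#' @param features numeric matrix with [feature_names()] columns
#' @param path CSV path
#' @return `path` (write) or the matrix (read)
#' @export
write_features_csv <- function(features, path) {
  stopifnot(identical(colnames(features), feature_names()))
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  stopifnot(identical(colnames(m), feature_names()))
  m
}
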