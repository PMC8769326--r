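#' Short-time frame energy
#'
#' Computes the energy of overlapping rectangular frames,
#' `E(j) = sum(x[i]^2)` over the samples of frame `j`. Frame `j` (0-based)
#' covers samples `[j*hop, j*hop + N_frame)`; the number of frames is
#' `floor((N_total - N_frame)/hop) + 1`.
#'
#' @param rec a [recording()] (16 kHz expected for the default pipeline)
#' @param frame_length frame length in seconds (default 0.020)
#' @param overlap fractional overlap between consecutive frames (default 0.5)
#' @return an `EnergySeries`: list with `E` (per-frame energy),
#'   `frame_length`, `overlap`, `n_frame`, `hop` (samples) and `sample_rate`
#' @export
frame_energy <- function(rec, frame_length = 0.020, overlap = 0.5) {
  stopifnot(inherits(rec, "Recording"), frame_length > 0,
            overlap >= 0, overlap < 1)
  n_frame <- round(frame_length * rec$sample_rate)
  hop <- round(n_frame * (1 - overlap))
  x <- rec$samples
  if (length(x) < n_frame)
    stop("recording shorter than one frame (", n_frame, " samples)")
  n_frames <- (length(x) - n_frame) %/% hop + 1L
  x2 <- x * x
  if (n_frame %% hop == 0) {
    # frame = k whole hop-blocks: sum hop-sized blocks once, then combine
    k <- n_frame %/% hop
    n_blocks <- length(x2) %/% hop
    bs <- colSums(matrix(x2[seq_len(n_blocks * hop)], nrow = hop))
    E <- vapply(seq_len(n_frames),
                function(j) sum(bs[j:(j + k - 1L)]), numeric(1))
  } else {
    E <- vapply(seq_len(n_frames), function(j) {
      i0 <- (j - 1L) * hop
      sum(x2[(i0 + 1L):(i0 + n_frame)])
    }, numeric(1))
  }
  structure(list(E = E, frame_length = frame_length, overlap = overlap,
                 n_frame = n_frame, hop = hop,
                 sample_rate = rec$sample_rate),
            class = "EnergySeries")
}

#' Energy histogram of a recording (dB scale)
#'
#' Bins the per-frame energies on a decibel scale,
#' `10*log10(E + eps)`. The modal bin estimates the background-noise level
#' of the recording; the event threshold is derived from the histogram's
#' right tail.
#'
#' @param es an `EnergySeries` from [frame_energy()]
#' @param n_bins number of equal-width dB bins (default 100)
#' @param eps floor added before taking logs
#' @return an `EnergyHistogram`: list with `bin_edges_db`, `mids_db`,
#'   `counts`, `modal_bin` (index of the count maximum)
#' @export
build_histogram <- function(es, n_bins = 100, eps = 1e-12) {
  stopifnot(inherits(es, "EnergySeries"), length(es$E) > 0)
  e_db <- 10 * log10(es$E + eps)
  rng <- range(e_db)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(n_bins, pmax(1L, findInterval(e_db, edges,
                                            rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges_db = edges,
                 mids_db = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 modal_bin = which.max(counts)),
            class = "EnergyHistogram")
}

#' Recording-adaptive detection thresholds from the energy histogram
#'
#' The event threshold `th1` is `A` times the energy of the highest-energy
#' bin, right of the modal (background) bin, whose count still reaches
#' `B` times the modal count — i.e. `A` scaled onto the level at which the
#' histogram's right tail decays to the fraction `B` of its peak. The onset
#' and offset thresholds have fixed ratios to `th1` floored at the modal
#' (background) energy:
#' `th2 = max(0.15*th1, E_mode)`, `th3 = max(0.01*th1, E_mode)`.
#' All three are returned in linear energy units; `th3 <= th2 <= th1` is
#' enforced.
#'
#' @param hist an `EnergyHistogram`
#' @param A multiplicative gap between the noise tail and the event
#'   threshold (linear energy; default 100, calibrated on the synthetic
#'   training split so that the hysteresis floors th2/th3 clear the
#'   background-energy bulk)
#' @param B tail-count fraction of the modal count (default 0.08)
#' @return an `EnergyThresholds` list: `th1`, `th2`, `th3` (linear energy),
#'   plus `A`, `B` and the tail/modal dB levels used
#' @export
compute_thresholds <- function(hist, A = 100, B = 0.08) {
  stopifnot(inherits(hist, "EnergyHistogram"), A > 0, B > 0, B < 1)
  counts <- hist$counts
  mode_i <- hist$modal_bin
  modal_db <- hist$mids_db[mode_i]
  modal_E <- 10^(modal_db / 10)
  # noise-tail quantile: walk right from the modal (background) bin until
  # the count first falls below B x the modal count; the last bin before
  # that crossing marks where the background peak ends
  right <- seq(mode_i, length(counts))
  below <- counts[right] < B * counts[mode_i]
  if (below[1] || length(right) == 1) {
    warning("no bin right of the mode reaches the B count criterion; ",
            "falling back to modal energy")
    tail_db <- modal_db
  } else {
    cross <- which(below)[1]
    tail_db <- hist$mids_db[right[if (is.na(cross)) length(right)
                                  else cross - 1L]]
  }
  th1 <- A * 10^(tail_db / 10)
  if (th1 <= modal_E)
    stop("th1 (", signif(th1, 4), ") does not exceed the modal background ",
         "energy (", signif(modal_E, 4), "); increase A")
  th2 <- max(0.15 * th1, modal_E)
  th3 <- max(0.01 * th1, modal_E)
  th2 <- min(th2, th1); th3 <- min(th3, th2)
  structure(list(th1 = th1, th2 = th2, th3 = th3, A = A, B = B,
                 tail_db = tail_db, modal_db = modal_db),
            class = "EnergyThresholds")
}

#' Detect duration-filtered sound events from an energy series
#'
#' An event is triggered wherever the frame energy rises above `th1`. Its
#' onset is found by scanning left from the trigger to the last frame with
#' energy below `th2` and its offset by scanning right to the first frame
#' below `th3` (hysteresis). Frame spans are converted to 0-based half-open
#' sample indices; events outside the `[min_dur, max_dur]` duration window
#' are dropped. Returned events are sorted and non-overlapping.
#'
#' @param es an `EnergySeries`
#' @param th an `EnergyThresholds`
#' @param min_dur,max_dur duration filter in seconds (defaults 0.15 and 1.1,
#'   the usual cough length bounds)
#' @param rec optional [recording()]; when supplied each event carries its
#'   waveform slice
#' @return data.frame of class `SoundEvents` with columns `start_sample`,
#'   `end_sample`, `start_s`, `end_s`, `peak_energy` and (when `rec` is
#'   given) a `samples` list-column
#' @export
detect_events <- function(es, th, min_dur = 0.15, max_dur = 1.1, rec = NULL) {
  stopifnot(inherits(es, "EnergySeries"), inherits(th, "EnergyThresholds"))
  E <- es$E
  hop <- es$hop; n_frame <- es$n_frame; fs <- es$sample_rate
  above <- which(E >= th$th1)
  out <- list()
  last_end_frame <- -1L
  for (j in above) {
    if (j <= last_end_frame) next
    a <- j
    while (a > 1L && E[a - 1L] >= th$th2) a <- a - 1L
    b <- j
    while (b < length(E) && E[b + 1L] >= th$th3) b <- b + 1L
    last_end_frame <- b
    start_sample <- (a - 1L) * hop
    end_sample <- (b - 1L) * hop + n_frame
    dur <- (end_sample - start_sample) / fs
    if (dur < min_dur || dur > max_dur) next
    out[[length(out) + 1L]] <-
      data.frame(start_sample = start_sample, end_sample = end_sample,
                 start_s = start_sample / fs, end_s = end_sample / fs,
                 peak_energy = max(E[a:b]))
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(start_sample = integer(0), end_sample = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               peak_energy = numeric(0))
  if (!is.null(rec) && nrow(ev) > 0) {
    ev$samples <- lapply(seq_len(nrow(ev)), function(i)
      rec$samples[(ev$start_sample[i] + 1L):ev$end_sample[i]])
  }
  class(ev) <- c("SoundEvents", "data.frame")
  ev
}

#' Run the full detector on a recording
#'
#' Convenience wrapper: [frame_energy()] then [build_histogram()],
#' [compute_thresholds()] and [detect_events()], attaching waveform slices.
#'
#' @inheritParams frame_energy
#' @inheritParams compute_thresholds
#' @inheritParams detect_events
#' @return a `SoundEvents` data.frame (see [detect_events()])
#' @export
detect_recording <- function(rec, frame_length = 0.020, overlap = 0.5,
                             A = 100, B = 0.08, n_bins = 100,
                             min_dur = 0.15, max_dur = 1.1) {
  es <- frame_energy(rec, frame_length, overlap)
  th <- compute_thresholds(build_histogram(es, n_bins), A = A, B = B)
  detect_events(es, th, min_dur, max_dur, rec = rec)
}

#' Write detected events as CSV
#'
#' @param events a `SoundEvents` data.frame
#' @param path output CSV path
#' @param subject_id subject column value
#' @return `path`, invisibly
#' @export
write_events_csv <- function(events, path, subject_id = "unknown") {
  df <- data.frame(subject_id = rep(subject_id, nrow(events)),
                   start_s = events$start_s, end_s = events$end_s,
                   peak_energy = events$peak_energy)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
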