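#' Recording objects
#'
#' A `Recording` is a plain list holding a mono waveform (`samples`, values in
#' \[-1, 1\]), its `sample_rate` in Hz, a `subject_id`, and optional
#' `lights_off`/`lights_on` markers in seconds.
#'
#' @param samples numeric waveform
#' @param sample_rate sampling rate in Hz (> 0)
#' @param subject_id subject identifier
#' @param lights_off,lights_on optional lights-out window in seconds
#' @return an object of class `Recording`
#' @export
recording <- function(samples, sample_rate, subject_id = "unknown",
                      lights_off = NULL, lights_on = NULL) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  dur <- length(samples) / sample_rate
  if (!is.null(lights_off) || !is.null(lights_on)) {
    stopifnot(!is.null(lights_off), !is.null(lights_on),
              lights_off >= 0, lights_off < lights_on, lights_on <= dur)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 subject_id = subject_id,
                 lights_off = lights_off, lights_on = lights_on),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording %s: %.1f s @ %g Hz>\n", x$subject_id,
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Load a WAV file as a Recording
#'
#' Stereo (or multi-channel) files are downmixed to mono by averaging the
#' channels. Sample values are normalised to \[-1, 1\]; the file's sampling
#' rate is preserved.
#'
#' @param path path to a readable WAV file
#' @param subject_id subject identifier attached to the recording (defaults
#'   to the file name without extension)
#' @return a [recording()] object
#' @export
load_audio <- function(path, subject_id = NULL) {
  w <- read_wav(path)
  if (nrow(w$samples) == 0) stop("empty WAV file: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  recording(rowMeans(w$samples), w$sample_rate, subject_id = subject_id)
}

#' Pre-process a recording: DC removal and down-sampling to 16 kHz
#'
#' DC removal subtracts the global mean (optionally a 10 Hz first-order
#' high-pass instead). Down-sampling uses a Kaiser-windowed polyphase
#' anti-aliasing filter. Input below the target rate is rejected — the
#' pipeline never upsamples.
#'
#' @param rec a [recording()] object
#' @param target_rate output sampling rate in Hz (default 16000)
#' @param highpass if `TRUE`, use a 10 Hz single-pole high-pass for DC
#'   removal instead of mean subtraction
#' @return a [recording()] at `target_rate` with zero-mean samples
#' @export
preprocess <- function(rec, target_rate = 16000, highpass = FALSE) {
  stopifnot(inherits(rec, "Recording"))
  x <- rec$samples
  if (length(x) == 0) stop("empty recording")
  if (rec$sample_rate < target_rate)
    stop("sample rate ", rec$sample_rate, " Hz is below the ", target_rate,
         " Hz target; upsampling is not supported")
  if (highpass) {
    # y[n] = a (y[n-1] + x[n] - x[n-1]), single pole at 10 Hz
    a <- 1 / (1 + 2 * pi * 10 / rec$sample_rate)
    x <- stats::filter(a * c(x[1], diff(x)), a, method = "recursive")
    x <- as.numeric(x)
  } else {
    x <- x - mean(x)
  }
  if (rec$sample_rate > target_rate) {
    x <- .resample_kernel(x, rec$sample_rate, target_rate)
    x <- x - mean(x)  # resampling can reintroduce a tiny offset
  }
  recording(x, target_rate, subject_id = rec$subject_id,
            lights_off = rec$lights_off, lights_on = rec$lights_on)
}
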