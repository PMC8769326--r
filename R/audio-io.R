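#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 8/16/24-bit integer PCM and 32-bit float
#' files. Samples are returned as a numeric matrix (channels in columns)
#' normalised to \[-1, 1\].
#'
#' @param path path to a `.wav` file
#' @return list with `samples` (numeric matrix, one column per channel) and
#'   `sample_rate` (Hz)
#' @keywords internal
read_wav <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0)
    stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(fmt_raw[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(fmt_raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt/data chunk): ", path)

  nch <- fmt$n_channels
  x <- switch(as.character(fmt$bits),
    "8"  = (as.integer(data_raw) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      b <- as.integer(data_raw)
      n <- length(b) %/% 3
      i <- 3 * (seq_len(n) - 1)
      v <- b[i + 1] + b[i + 2] * 256 + b[i + 3] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = if (fmt$audio_format == 3) {
      readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) / 4, 4,
              endian = "little") / 2147483648
    },
    stop("unsupported WAV bit depth: ", fmt$bits))
  n_frames <- length(x) %/% nch
  samples <- matrix(x[seq_len(n_frames * nch)], ncol = nch, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Write a mono or multi-channel PCM 16-bit WAV file
#'
#' @param x numeric vector (mono) or matrix (channels in columns), values
#'   clipped to \[-1, 1\]
#' @param path output path
#' @param sample_rate sampling rate in Hz
#' @return `path`, invisibly
#' @export
write_wav <- function(x, path, sample_rate) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  x[] <- pmin(1, pmax(-1, c(x)))     # clip in place, keeping dimensions
  nch <- ncol(x)
  pcm <- as.integer(round(t(x) * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2L), con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
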