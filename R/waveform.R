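#' Sampled audio waveform
#'
#' The basic currency of stimulus synthesis and vocoding: a mono sequence of
#' linear-amplitude samples plus a sampling rate. Stimuli in this package are
#' nominally generated at 22.05 kHz / 16 bit, but any rate is accepted.
#'
#' @param samples Numeric vector of finite sample values (linear amplitude).
#' @param rate Sampling rate in Hz (> 0). Default 22050.
#' @return An object of class `"waveform"`: a list with elements `samples`
#'   and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 22050)))
#' duration(w)
#' @export
waveform <- function(samples, rate = 22050) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f ms), rms %.4g\n",
              length(x$samples), x$rate, 1000 * duration(x), rms(x)))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  t <- seq_along(x$samples) / x$rate
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "amplitude", ...)
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param x A `waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(x) length(x$samples) / x$rate

#' Root-mean-square amplitude
#' @param x A `waveform` or numeric vector.
#' @return RMS of the samples.
#' @export
rms <- function(x) {
  s <- if (inherits(x, "waveform")) x$samples else as.numeric(x)
  sqrt(mean(s^2))
}

## ---- RIFF/WAVE I/O ---------------------------------------------------------
## Minimal mono WAV support: PCM 16-bit (format 1) and IEEE float 32 (format 3).
## Chunk-walking reader so extra chunks (LIST, fact, ...) are tolerated.

#' Read a mono WAV file
#'
#' Supports RIFF/WAVE with 16-bit integer PCM or 32-bit IEEE-float samples.
#' Multi-channel files are rejected unless `down_mix = TRUE`, in which case
#' channels are averaged.
#'
#' @param path Path to a `.wav` file.
#' @param down_mix Average channels of a multi-channel file instead of
#'   raising an error. Default `FALSE`.
#' @return A [waveform] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path, down_mix = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      hdr <- function(off) {
        sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      }
      fmt <- list(
        code = hdr(0L),
        channels = hdr(2L),
        rate = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits = hdr(14L)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt/data chunk")

  if (fmt$code == 1L && fmt$bits == 16L) {
    s <- readBin(data_raw, "integer", length(data_raw) %/% 2L,
                 size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    s <- readBin(data_raw, "double", length(data_raw) %/% 4L,
                 size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$code, ", ", fmt$bits, " bit)")
  }

  if (fmt$channels > 1L) {
    if (!down_mix) {
      stop("multi-channel WAV; pass down_mix = TRUE to average channels")
    }
    s <- colMeans(matrix(s, nrow = fmt$channels))
  }
  waveform(s, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param path Output path.
#' @param x A [waveform]; samples are expected in `[-1, 1]` (clipped with a
#'   warning otherwise).
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float). Default 16.
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, x, bit_depth = 16) {
  stopifnot(inherits(x, "waveform"))
  if (!bit_depth %in% c(16, 32)) stop("bit_depth must be 16 or 32")
  s <- x$samples
  if (bit_depth == 16 && any(abs(s) > 1)) {
    warning("samples outside [-1, 1] clipped on write")
    s <- pmin(1, pmax(-1, s))
  }
  n <- length(s)
  bytes_per <- bit_depth / 8
  data_sz <- n * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")

  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_sz)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16)
  w16(fmt_code); w16(1)                      # mono
  w32(round(x$rate))
  w32(round(x$rate) * bytes_per)             # byte rate
  w16(bytes_per); w16(bit_depth)
  writeChar("data", con, eos = NULL)
  w32(data_sz)
  if (bit_depth == 16) {
    q <- as.integer(round(s * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(s, con, size = 4, endian = "little")
  }
  invisible(path)
}
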