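#' Audio signal container
#'
#' Minimal container for mono audio: a numeric sample vector plus a sampling
#' rate in Hz. All signal-processing functions in the package operate on this
#' class. Samples are dimensionless amplitudes, nominally in -1..1.
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param rate Sampling rate in Hz (scalar > 0).
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive finite number", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite and non-missing", call. = FALSE)
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.1f ms)>\n",
              length(x$samples), x$rate, duration_ms(x)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in milliseconds
#' @param x An `audio_signal`.
#' @return Duration in ms.
#' @export
duration_ms <- function(x) 1000 * length(x$samples) / x$rate

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files with PCM 16- or 24-bit integer or IEEE float32
#' samples. Only mono files are accepted; multi-channel material must be
#' mixed down upstream.
#'
#' @param path Path to a .wav file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = sum(as.integer(raw[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(raw[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path, call. = FALSE)
  if (fmt$channels != 1L) stop("only mono WAV supported (got ", fmt$channels, " channels)", call. = FALSE)

  n <- length(data_raw)
  samples <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n %/% 2, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- n %/% 3
    b <- matrix(as.integer(data_raw[seq_len(3 * m)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", n %/% 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bit)", call. = FALSE)
  }
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param x An [audio_signal()].
#' @param path Output path.
#' @param bits 16 (PCM, values clipped to -1..1) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16L) {
  stopifnot(inherits(x, "audio_signal"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) stop("`bits` must be 16 or 32", call. = FALSE)
  n <- length(x$samples)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  fmt_tag <- if (bits == 16L) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(x$rate), con, 4, endian = "little")
  writeBin(as.integer(x$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    v <- pmin(pmax(x$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(v * 32768)), con, 2, endian = "little")
  } else {
    writeBin(x$samples, con, 4, endian = "little")
  }
  invisible(path)
}
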