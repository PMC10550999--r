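# Minimal RIFF/WAVE reader and writer.
#
# Tag audio moves through the pipeline as WAV because it is the one portable
# uncompressed container every acoustics toolchain understands. Only the two
# encodings the tags and the synthetic generator produce are supported:
# 16-bit integer PCM (format code 1) and 32-bit IEEE float (format code 3).
# Float is the round-trip-exact default for synthetic deployments; PCM16
# mirrors the real tag recordings.

#' Read a WAV file
#'
#' Supports mono or multi-channel 16-bit PCM and 32-bit float WAV. Samples
#' are returned on the normalised full scale (-1, 1): PCM16 samples are
#' divided by 32768, float samples are taken as-is.
#'
#' @param path path to a `.wav` file.
#' @return list with `samples` (numeric matrix, one column per channel),
#'   `fs` (sampling rate, Hz) and `bits` (bit depth).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        code = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$code == 1 && fmt$bits == 16) {
        n <- size %/% 2
        raw <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
        samples <- raw / 32768
      } else if (fmt$code == 3 && fmt$bits == 32) {
        n <- size %/% 4
        samples <- readBin(con, "numeric", n, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding: format code ", fmt$code,
             ", ", fmt$bits, " bits")
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  m <- matrix(samples, ncol = fmt$channels, byrow = TRUE)
  list(samples = m, fs = fmt$fs, bits = fmt$bits)
}

#' Write a WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, on the normalised full scale (-1, 1).
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @param format `"float"` (32-bit IEEE, lossless for analysis round trips)
#'   or `"pcm16"` (16-bit integer, as recorded by the tags).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, format = c("float", "pcm16")) {
  format <- match.arg(format)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  nch <- ncol(samples)
  interleaved <- as.vector(t(samples))
  bytes_per <- if (format == "float") 4L else 2L
  data_size <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "float") 3L else 1L, con, 2, endian = "little")
  writeBin(as.integer(nch), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, 2, endian = "little")
  writeBin(if (format == "float") 32L else 16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float") {
    writeBin(interleaved, con, 4, endian = "little")
  } else {
    q <- pmax(pmin(round(interleaved * 32768), 32767), -32768)
    writeBin(as.integer(q), con, 2, endian = "little")
  }
  invisible(path)
}
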