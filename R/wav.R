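# Minimal mono PCM WAV I/O (RIFF little-endian, 16- or 32-bit integer).

#' Write a mono waveform to a PCM16 WAV file
#'
#' @param w a [waveform] object (samples in \[-1, 1\]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(pmin(w$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Supports 16- and 32-bit integer PCM, mono. Samples are rescaled to \[-1, 1\].
#'
#' @param path WAV file path.
#' @return a [waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, 2, endian = "little")
      channels <- readBin(con, "integer", 1, 2, endian = "little")
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (fmt != 1L) stop("only integer PCM WAV is supported")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      nb <- bits %/% 8L
      samples <- readBin(con, "integer", sz %/% nb, nb, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!is.null(channels) && channels != 1L) stop("only mono WAV is supported")
  scale <- if (bits == 16L) 32768 else 2147483648
  waveform(samples / scale, rate)
}
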