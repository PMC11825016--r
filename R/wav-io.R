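#' Write a waveform to a 16-bit PCM WAV file
#'
#' Pressure samples are scaled by `scale` (uPa per full-scale count) so the
#' calibration can be restored on read. The scale used is returned invisibly
#' and also embedded in nothing: keep it with the file's metadata (the
#' pipeline manifest records it).
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param scale uPa value mapped to full scale (32767). Default: peak of `w`.
#' @return Invisibly, the scale used.
#' @export
write_wav <- function(w, path, scale = NULL) {
  stopifnot(inherits(w, "waveform"))
  scale <- scale %||% max(abs(w$samples), 1e-12)
  x <- round(w$samples / scale * 32767)
  x <- pmin(pmax(x, -32768), 32767)
  n <- length(x)
  fs <- as.integer(round(w$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.integer(x), con, size = 2, endian = "little")
  invisible(scale)
}

#' Read a 16-bit PCM WAV file as a waveform
#'
#' @param path WAV file path (mono, 16-bit PCM).
#' @param scale uPa per full-scale count (inverse of the `scale` used at
#'   write time). Default 1 returns counts/32767.
#' @param start_time Optional `POSIXct` start.
#' @return A [waveform()].
#' @export
read_wav <- function(path, scale = 1, start_time = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAV file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) abort("not a WAVE file")
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L || bits != 16L) abort("only 16-bit PCM WAV is supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      samples <- readBin(con, "integer", sz / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(samples)) abort("no data chunk found")
  if (!is.null(channels) && channels != 1L) abort("only mono WAV is supported")
  waveform(samples / 32767 * scale, fs, start_time)
}
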