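# Minimal RIFF/WAVE PCM 16-bit I/O. No WAV reader is available among the
# package's dependencies, so the canonical chunk layout is written directly;
# only the uncompressed PCM16 subset used by the acquisition chain is
# supported.

#' Write a multi-channel waveform to a 16-bit PCM WAV file
#'
#' @param x numeric matrix, samples x channels (a vector is one channel),
#'   values in [-1, 1]; values outside are clipped.
#' @param path output file.
#' @param fs sample rate, Hz.
#' @return invisibly, the path.
#' @export
write_wav <- function(x, path, fs = 100e3) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  nch <- ncol(x); nsamp <- nrow(x)
  pcm <- as.integer(round(pmax(-1, pmin(1, t(x))) * 32767))
  data_bytes <- nsamp * nch * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * 2), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with \code{x} (samples x channels matrix, values in [-1, 1])
#'   and \code{fs} (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; nch <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV supported")
      nch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit WAV supported")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      x <- t(matrix(pcm / 32767, nrow = nch))
    } else {
      readBin(con, raw(), n = sz)
    }
    if (!is.null(x) && !is.null(fs)) break
  }
  if (is.null(x)) stop("no data chunk found")
  list(x = x, fs = fs)
}
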