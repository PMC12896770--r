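# Minimal PCM-16 WAV I/O. Only what the cohort format needs: mono or
# multi-channel 16-bit linear PCM, little-endian RIFF.

#' Write a waveform as 16-bit PCM WAV
#'
#' @param samples Numeric vector (mono) or matrix with one row per channel,
#'   values in \[-1, 1\] (clipped if outside).
#' @param path Output file path.
#' @param sample_rate Sample rate in Hz.
#' @return `path`, invisibly.
#' @export
wav_write <- function(samples, path, sample_rate) {
  if (is.matrix(samples)) {
    n_chan <- nrow(samples)
    interleaved <- as.vector(samples) # column-major = frame-major interleave
  } else {
    n_chan <- 1L
    interleaved <- samples
  }
  x <- pmax(-1, pmin(1, interleaved))
  pcm <- as.integer(round(x * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * n_chan * 2L, con, size = 4, endian = "little")
  writeBin(n_chan * 2L, con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric vector for mono, channels-by-frames
#'   matrix otherwise, in \[-1, 1\]) and `sample_rate`.
#' @export
wav_read <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", size = 2, endian = "little"),
        n_chan = readBin(con, "integer", size = 2, endian = "little"),
        sr     = readBin(con, "integer", size = 4, endian = "little"),
        brate  = readBin(con, "integer", size = 4, endian = "little"),
        align  = readBin(con, "integer", size = 2, endian = "little"),
        bits   = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(fmt) || is.null(pcm)) stop("malformed WAV (missing chunk): ", path)
  if (fmt$format != 1L || fmt$bits != 16L)
    stop("unsupported WAV encoding (need 16-bit PCM): ", path)
  x <- pcm / 32767
  if (fmt$n_chan > 1L) x <- matrix(x, nrow = fmt$n_chan)
  list(samples = x, sample_rate = fmt$sr)
}
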