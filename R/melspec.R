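# Log-Mel spectrogram frontend: each 2560-sample (160 ms, 16 kHz) segment
# becomes an 80-band x 41-frame dB matrix. STFT: 256-sample Hann window,
# hop 64, centered (reflect-padded) framing -> 1 + floor(2560/64) = 41
# frames. Power spectra are projected onto a Slaney-style mel filterbank
# (0-8000 Hz, area-normalized) and converted to dB referenced to the
# per-segment maximum, floored at -80 dB. Referencing to the maximum makes
# the representation invariant to positive rescaling of the input.

hz_to_mel <- function(f) {
  # Slaney: linear below 1 kHz, logarithmic above
  ifelse(f < 1000, f / (200 / 3),
         15 + log(pmax(f, 1000) / 1000) / (log(6.4) / 27))
}

mel_to_hz <- function(m) {
  ifelse(m < 15, m * 200 / 3, 1000 * exp((m - 15) * log(6.4) / 27))
}

#' Slaney-style mel filterbank
#'
#' @param n_mels Number of mel bands.
#' @param n_fft FFT length (bins used: `n_fft/2 + 1`).
#' @param sr Sample rate, Hz.
#' @param fmin,fmax Frequency range of the filterbank, Hz.
#' @return `n_mels x (n_fft/2 + 1)` matrix of non-negative triangular
#'   weights, area-normalized, with attribute `centers` (Hz).
#' @export
mel_filterbank <- function(n_mels = .ddk$n_mels, n_fft = .ddk$n_fft,
                           sr = .ddk$sr, fmin = 0, fmax = .ddk$fmax) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (0:(n_bins - 1L)) * sr / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (i in seq_len(n_mels)) {
    lo <- pts[i]; ce <- pts[i + 1L]; hi <- pts[i + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  attr(fb, "centers") <- pts[2:(n_mels + 1L)]
  fb
}

# log-mel spectrogram of an arbitrary-length 16 kHz waveform (internal;
# the public contract fixes the length to one segment)
melspec_any <- function(x, fb = NULL) {
  n <- length(x)
  pad <- .ddk$n_fft %/% 2L
  if (n <= pad) stop("waveform too short for centered framing")
  padded <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  n_frames <- 1L + n %/% .ddk$hop
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(.ddk$n_fft - 1L)) / .ddk$n_fft)
  frames <- vapply(0:(n_frames - 1L), function(k) {
    padded[(k * .ddk$hop + 1L):(k * .ddk$hop + .ddk$n_fft)] * w
  }, numeric(.ddk$n_fft))
  spec <- stats::mvfft(frames)
  power <- Mod(spec[1:(.ddk$n_fft %/% 2L + 1L), , drop = FALSE])^2
  if (is.null(fb)) fb <- mel_filterbank()
  m <- fb %*% power
  ref <- max(m)
  if (ref <= 0) return(matrix(.ddk$db_floor, nrow(m), ncol(m)))
  pmax(10 * log10(pmax(m, ref * 1e-12) / ref), .ddk$db_floor)
}

#' Compute the 80x41 log-Mel spectrogram of one segment
#'
#' @param segment Numeric vector of exactly 2560 samples (one 160 ms segment
#'   at 16 kHz).
#' @param fb Optional precomputed [mel_filterbank()] (avoids recomputation
#'   in batch use).
#' @return `mel_spectrogram`: an 80x41 matrix in dB (max 0, floor -80) with
#'   attributes `band_centers` (Hz) and `frame_hop` (samples).
#' @export
compute_melspec <- function(segment, fb = NULL) {
  if (length(segment) != .ddk$seg_len)
    stop("segment must have exactly ", .ddk$seg_len, " samples, got ",
         length(segment))
  if (is.null(fb)) fb <- mel_filterbank()
  m <- melspec_any(segment, fb)
  structure(m, band_centers = attr(fb, "centers"), frame_hop = .ddk$hop,
            class = c("mel_spectrogram", "matrix"))
}

#' Compute log-Mel spectrograms for a batch of segments
#'
#' Elementwise application of [compute_melspec()] preserving order and
#' provenance.
#' @param segments A `ddk_segments` object (see [segment_recording()]) or a
#'   2560 x k matrix.
#' @return List with `spec` (80 x 41 x k array) and `meta` (provenance data
#'   frame; `NULL` for a bare matrix input).
#' @export
batch_melspec <- function(segments) {
  if (inherits(segments, "ddk_segments")) {
    mat <- segments$samples
    meta <- segments$meta
  } else {
    mat <- segments
    meta <- NULL
  }
  k <- ncol(mat)
  fb <- mel_filterbank()
  arr <- array(0, dim = c(.ddk$n_mels, 1L + .ddk$seg_len %/% .ddk$hop, k))
  for (i in seq_len(k)) {
    arr[, , i] <- tryCatch(compute_melspec(mat[, i], fb),
                           error = function(e) stop("segment ", i, ": ",
                                                    conditionMessage(e)))
  }
  list(spec = arr, meta = meta)
}
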