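# Standardization and segmentation: peak-normalize, downmix to mono,
# resample to 16 kHz, then cut into 160 ms windows with 50 % overlap.
# Order matters only up to scaling; the whole pipeline is invariant to
# pre-scaling of the input by any positive constant.

#' Peak-normalize a recording
#'
#' Scales the waveform so that `max(abs(samples)) == 1`. Loudness differences
#' between speakers and sessions carry no diagnostic information here, so
#' they are removed before feature extraction.
#' @param recording An [audio_recording()].
#' @return The recording with unit peak amplitude.
#' @export
normalize_amplitude <- function(recording) {
  m <- max(abs(recording$samples))
  if (m == 0) stop("degenerate input: all-zero signal cannot be normalized")
  recording$samples <- recording$samples / m
  recording
}

#' Downmix to mono
#'
#' Multi-channel audio is reduced to a single channel by the arithmetic mean
#' across channels; mono input passes through unchanged.
#' @param recording An [audio_recording()].
#' @return Mono recording.
#' @export
to_mono <- function(recording) {
  if (is.matrix(recording$samples)) {
    recording$samples <- colMeans(recording$samples)
    recording$n_channels <- 1L
  }
  recording
}

#' Resample to the 16 kHz working rate
#'
#' Polyphase band-limited resampling (via [signal::resample()]). The output
#' length is forced to `round(n * 16000 / sr)` by trimming or zero-padding
#' at most one sample. 16 kHz input passes through untouched.
#' @param recording Mono [audio_recording()] with sample rate >= 8 kHz.
#' @return Recording at 16000 Hz.
#' @export
resample_to_16k <- function(recording) {
  sr <- recording$sample_rate
  if (sr < 8000) stop("unsupported sample rate (must be >= 8000 Hz): ", sr)
  if (sr == .ddk$sr) return(recording)
  if (is.matrix(recording$samples)) stop("resample_to_16k expects mono input")
  g <- gcd_int(.ddk$sr, sr)
  y <- signal::resample(recording$samples, .ddk$sr %/% g, sr %/% g)
  target <- round(length(recording$samples) * .ddk$sr / sr)
  if (length(y) > target) y <- y[seq_len(target)]
  if (length(y) < target) y <- c(y, numeric(target - length(y)))
  recording$samples <- as.numeric(y)
  recording$sample_rate <- .ddk$sr
  recording
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Cut a standardized recording into fixed 160 ms segments
#'
#' Windows of 2560 samples starting at 0, 1280, 2560, ... ; windows that
#' would extend past the end are dropped, so a recording of `n` samples
#' yields `floor((n - 2560) / 1280) + 1` segments (0 if `n < 2560`).
#'
#' @param recording Mono 16 kHz [audio_recording()].
#' @return A `ddk_segments` object: list with `samples` (2560 x k matrix)
#'   and `meta` (data frame: `parent`, `start_sample`, `subject_id`, `label`).
#' @export
segment_recording <- function(recording) {
  if (recording$sample_rate != .ddk$sr)
    stop("segment_recording expects a 16 kHz recording")
  if (is.matrix(recording$samples))
    stop("segment_recording expects mono input")
  x <- recording$samples
  n <- length(x)
  parent <- paste0(recording$subject_id, "/", recording$task_id)
  if (n < .ddk$seg_len) {
    warning("recording shorter than one segment (", n, " samples): ", parent)
    starts <- integer(0)
  } else {
    starts <- seq(0L, n - .ddk$seg_len, by = .ddk$seg_hop)
  }
  mat <- vapply(starts, function(s) x[(s + 1L):(s + .ddk$seg_len)],
                numeric(.ddk$seg_len))
  if (length(starts) == 0) mat <- matrix(numeric(0), nrow = .ddk$seg_len, ncol = 0)
  structure(
    list(samples = mat,
         meta = data.frame(parent = rep(parent, length(starts)),
                           start_sample = as.integer(starts),
                           subject_id = rep(recording$subject_id, length(starts)),
                           label = rep(recording$label, length(starts)),
                           stringsAsFactors = FALSE)),
    class = "ddk_segments")
}

#' Standardize one recording (normalize, mono, 16 kHz) and segment it
#' @param recording An [audio_recording()].
#' @return A `ddk_segments` object.
#' @export
preprocess_recording <- function(recording) {
  segment_recording(resample_to_16k(to_mono(normalize_amplitude(recording))))
}

#' Standardize and segment a whole cohort
#' @param cohort A `ddk_cohort`.
#' @return A combined `ddk_segments` object over all recordings.
#' @export
preprocess_cohort <- function(cohort) {
  parts <- lapply(cohort, preprocess_recording)
  structure(
    list(samples = do.call(cbind, lapply(parts, `[[`, "samples")),
         meta = do.call(rbind, lapply(parts, `[[`, "meta"))),
    class = "ddk_segments")
}
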