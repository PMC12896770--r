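# Independent oracles and small fixture builders used across the suite.

# Count syllable pulses of a waveform: local maxima of the 20 ms-smoothed
# magnitude envelope above half its maximum, merging maxima closer than
# 60 ms (one syllable cannot be shorter than its pulse).
count_envelope_peaks <- function(x, sr = 16000) {
  w <- round(0.020 * sr)
  sm <- stats::filter(abs(x), rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- 0
  pk <- which(diff(sign(diff(sm))) == -2) + 1
  pk <- pk[sm[pk] > 0.5 * max(sm)]
  if (length(pk) == 0) return(0L)
  length(pk[c(TRUE, diff(pk) > 0.060 * sr)])
}

# Step-wise shape trace: channels and floor-halved spatial dims through n
# conv blocks (independent of flatten_dim()).
trace_flatten <- function(h, w, n_layers) {
  ch <- 1
  for (l in seq_len(n_layers)) {
    ch <- if (l == 1) 4 else 2 * ch
    h <- floor(h / 2)
    w <- floor(w / 2)
    stopifnot(h > 0, w > 0)
  }
  ch * h * w
}

# Per-layer closed-form parameter count: (k*k*c_in + 1)*c_out for convs,
# (d_in + 1)*d_out for affine layers.
count_params_oracle <- function(channels, fc_dims) {
  conv <- sum((9 * channels[-length(channels)] + 1) * channels[-1])
  fc <- sum((fc_dims[-length(fc_dims)] + 1) * fc_dims[-1])
  conv + fc
}

# Slaney mel center table derived from the piecewise-linear/log mapping,
# written out independently of the package's filterbank code.
slaney_centers <- function(n_mels = 80, fmin = 0, fmax = 8000) {
  to_mel <- function(f) ifelse(f < 1000, 3 * f / 200,
                               15 + 27 * log(f / 1000) / log(6.4))
  to_hz <- function(m) ifelse(m < 15, 200 * m / 3,
                              1000 * exp(log(6.4) * (m - 15) / 27))
  pts <- to_hz(seq(to_mel(fmin), to_mel(fmax), length.out = n_mels + 2))
  pts[2:(n_mels + 1)]
}

# Hand-built dataset of k spectrogram "items" with alternating labels;
# values uniform in (-60, -10) so no cell collides with a mask fill value.
make_tiny_dataset <- function(k, seed = 1, with_segments = FALSE) {
  set.seed(seed)
  spec <- array(runif(80 * 41 * k, -60, -10), dim = c(80, 41, k))
  meta <- data.frame(
    parent = sprintf("rec%d", seq_len(k)),
    start_sample = rep(0L, k),
    subject_id = sprintf("S%d", seq_len(k)),
    label = rep(c("PD", "HC"), length.out = k),
    stringsAsFactors = FALSE)
  segs <- if (with_segments)
    matrix(runif(2560 * k, -1, 1), nrow = 2560) else NULL
  structure(list(segments = segs, spec = spec, meta = meta),
            class = "ddk_dataset")
}

# small cohorts reused by several files (built once per test run)
tiny_cohort_cache <- new.env(parent = emptyenv())

tiny_separable_dataset <- function() {
  if (is.null(tiny_cohort_cache$sep)) {
    co <- generate_cohort(cohort_spec(
      n_subjects_per_class = 6L, recordings_per_subject = 1L,
      duration_s = 1.5, seed = 77L))
    tiny_cohort_cache$sep <- prepare_dataset(co)
  }
  tiny_cohort_cache$sep
}
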