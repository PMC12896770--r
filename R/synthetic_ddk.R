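# Synthetic diadochokinetic (DDK) speech cohorts.
#
# Stand-in for restricted clinical corpora: each recording is a train of
# syllable-like pulses (10 ms noise burst + exponentially decaying harmonic
# complex) amplitude-modulated at the subject's syllable rate, with
# per-syllable timing jitter and additive background noise. The PD class
# draws its syllable rate, modulation depth, and noise level from
# deficit-shifted distributions, mimicking the slowed, irregular, and less
# modulated DDK performance seen in hypokinetic dysarthria. With all
# deficits at zero the two classes are drawn from identical distributions.

#' Specification of a synthetic DDK cohort
#'
#' @param n_subjects_per_class Subjects per class (PD and HC).
#' @param recordings_per_subject DDK recordings per subject.
#' @param duration_s Recording duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param hc_syllable_rate Healthy-control mean syllable rate, syllables/s.
#' @param pd_rate_deficit Rate reduction (syllables/s) applied to the PD class.
#' @param hc_mod_depth Healthy-control amplitude-modulation depth in \[0, 1\].
#' @param pd_mod_depth_deficit Modulation-depth reduction for the PD class.
#' @param pd_noise_excess Additional background-noise amplitude (linear) for PD.
#' @param subject_sd Between-subject SD of the syllable-rate random effect
#'   (syllables/s); the modulation-depth random effect uses `0.15 * subject_sd`.
#' @param seed Master seed; identical spec + seed gives a bit-identical cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects_per_class = 50L,
                        recordings_per_subject = 2L,
                        duration_s = 3,
                        sample_rate = 16000L,
                        hc_syllable_rate = 5.5,
                        pd_rate_deficit = 1.2,
                        hc_mod_depth = 0.90,
                        pd_mod_depth_deficit = 0.35,
                        pd_noise_excess = 0.02,
                        subject_sd = 0.35,
                        seed = 1L) {
  spec <- list(
    n_subjects_per_class = as.integer(n_subjects_per_class),
    recordings_per_subject = as.integer(recordings_per_subject),
    duration_s = duration_s, sample_rate = as.integer(sample_rate),
    hc_syllable_rate = hc_syllable_rate, pd_rate_deficit = pd_rate_deficit,
    hc_mod_depth = hc_mod_depth, pd_mod_depth_deficit = pd_mod_depth_deficit,
    pd_noise_excess = pd_noise_excess, subject_sd = subject_sd,
    seed = as.integer(seed)
  )
  chk <- function(ok, field, msg) if (!ok) stop("invalid cohort spec: `", field, "` ", msg)
  chk(spec$n_subjects_per_class >= 1, "n_subjects_per_class", "must be >= 1")
  chk(spec$recordings_per_subject >= 1, "recordings_per_subject", "must be >= 1")
  chk(spec$duration_s > 0, "duration_s", "must be positive")
  chk(spec$sample_rate >= 8000, "sample_rate", "must be >= 8000 Hz")
  chk(spec$hc_syllable_rate > 0, "hc_syllable_rate", "must be positive")
  chk(spec$pd_rate_deficit >= 0, "pd_rate_deficit", "must be non-negative")
  chk(spec$hc_syllable_rate - spec$pd_rate_deficit > 0, "pd_rate_deficit",
      "must leave a positive PD syllable rate")
  chk(spec$hc_mod_depth >= 0 && spec$hc_mod_depth <= 1, "hc_mod_depth",
      "must lie in [0, 1]")
  chk(spec$pd_mod_depth_deficit >= 0, "pd_mod_depth_deficit", "must be non-negative")
  chk(spec$hc_mod_depth - spec$pd_mod_depth_deficit >= 0, "pd_mod_depth_deficit",
      "must not exceed hc_mod_depth")
  chk(spec$pd_noise_excess >= 0, "pd_noise_excess", "must be non-negative")
  chk(spec$subject_sd >= 0, "subject_sd", "must be non-negative")
  class(spec) <- "cohort_spec"
  spec
}

#' A labeled, subject-tagged audio recording
#'
#' @param samples Numeric vector (mono) or channels-by-frames matrix in \[-1, 1\].
#' @param sample_rate Sample rate, Hz.
#' @param subject_id Subject identifier.
#' @param label Class label, `"PD"` or `"HC"`.
#' @param task_id Task identifier.
#' @return An `audio_recording` object.
#' @export
audio_recording <- function(samples, sample_rate, subject_id, label,
                            task_id = "ddk1") {
  if (!label %in% c("PD", "HC")) stop("label must be 'PD' or 'HC', got: ", label)
  structure(
    list(samples = samples, sample_rate = as.integer(sample_rate),
         n_channels = if (is.matrix(samples)) nrow(samples) else 1L,
         subject_id = as.character(subject_id), label = label,
         task_id = as.character(task_id)),
    class = "audio_recording")
}

# Background-noise amplitude common to both classes; PD adds pd_noise_excess.
.base_noise <- 0.01

# One subject's latent parameters, drawn from the class distribution.
draw_subject_params <- function(spec, label) {
  is_pd <- label == "PD"
  rate <- spec$hc_syllable_rate - if (is_pd) spec$pd_rate_deficit else 0
  rate <- rate + rnorm(1, 0, spec$subject_sd)
  rate <- min(max(rate, 1), 9)
  mod <- spec$hc_mod_depth - if (is_pd) spec$pd_mod_depth_deficit else 0
  mod <- mod + rnorm(1, 0, 0.15 * spec$subject_sd)
  mod <- min(max(mod, 0.05), 1)
  noise <- (.base_noise + if (is_pd) spec$pd_noise_excess else 0) * runif(1, 0.8, 1.2)
  f0 <- min(max(rnorm(1, 120, 15), 80), 200)
  # Timing irregularity grows with the configured rate deficit so that the
  # all-deficits-zero cohort is exactly class-symmetric.
  jitter_sd <- 0.008 + if (is_pd) 0.010 * spec$pd_rate_deficit else 0
  list(rate = rate, mod = mod, noise = noise, f0 = f0, jitter_sd = jitter_sd)
}

# Synthesize one DDK pulse-train recording from subject parameters.
synth_ddk_recording <- function(p, duration_s, sr) {
  n <- round(duration_s * sr)
  t <- (0:(n - 1)) / sr
  # harmonic complex carrier, 8 harmonics, 1/h amplitudes, random phases
  carrier <- numeric(n)
  for (h in 1:8) {
    fh <- h * p$f0
    if (fh < sr / 2) carrier <- carrier + sin(2 * pi * fh * t + runif(1, 0, 2 * pi)) / h
  }
  carrier <- carrier / max(abs(carrier))
  # syllable onsets at the subject rate with Gaussian timing jitter
  period <- 1 / p$rate
  k_max <- floor((duration_s - 0.07) / period)
  onsets <- (0:k_max) * period + rnorm(k_max + 1, 0, p$jitter_sd)
  onsets <- onsets[onsets >= 0 & onsets <= duration_s - 0.07]
  # pulse envelope: 10 ms linear attack, 60 ms exponential decay (tau 25 ms)
  atk <- round(0.010 * sr); dec <- round(0.060 * sr)
  pulse <- c(seq(0, 1, length.out = atk), exp(-(1:dec) / (0.025 * sr)))
  env <- numeric(n)
  bursts <- numeric(n)
  burst_len <- round(0.010 * sr)
  for (on in onsets) {
    i0 <- round(on * sr) + 1L
    idx <- i0:min(i0 + length(pulse) - 1L, n)
    env[idx] <- pmax(env[idx], pulse[seq_along(idx)])
    bidx <- i0:min(i0 + burst_len - 1L, n)
    bursts[bidx] <- bursts[bidx] + 0.4 * rnorm(length(bidx))
  }
  env <- (1 - p$mod) + p$mod * env
  x <- 0.85 * env * carrier + env * bursts + p$noise * rnorm(n)
  pmax(-1, pmin(1, x))
}

#' Generate a synthetic two-class DDK cohort
#'
#' Produces `2 * n_subjects_per_class` subjects, each with
#' `recordings_per_subject` pseudo-DDK recordings. One RNG stream per
#' subject is derived by counter from the master seed, so enlarging the
#' cohort does not reshuffle existing subjects.
#'
#' @param spec A [cohort_spec()].
#' @return A `ddk_cohort`: list of [audio_recording()] objects with the spec
#'   attached as an attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  for (label in c("HC", "PD")) {
    offset <- if (label == "HC") 0L else 100000L
    for (i in seq_len(spec$n_subjects_per_class)) {
      sid <- sprintf("%s%03d", label, i)
      recs_i <- with_seed(derive_seed(spec$seed, offset + i), {
        p <- draw_subject_params(spec, label)
        lapply(seq_len(spec$recordings_per_subject), function(r) {
          audio_recording(
            synth_ddk_recording(p, spec$duration_s, spec$sample_rate),
            spec$sample_rate, sid, label, task_id = sprintf("ddk%d", r))
        })
      })
      recs <- c(recs, recs_i)
    }
  }
  structure(recs, class = "ddk_cohort", spec = spec)
}

#' Write a cohort as PCM-16 WAV files plus manifest
#'
#' @param cohort A `ddk_cohort` (or list of [audio_recording()]).
#' @param directory Output directory (created if missing).
#' @return The manifest data frame (`file`, `subject_id`, `label`, `task_id`),
#'   also written to `manifest.csv` in `directory`.
#' @export
write_cohort_wav <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    fname <- sprintf("%s_%s.wav", rec$subject_id, rec$task_id)
    wav_write(rec$samples, file.path(directory, fname), rec$sample_rate)
    data.frame(file = fname, subject_id = rec$subject_id, label = rec$label,
               task_id = rec$task_id, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), subject_id = character(),
               label = character(), task_id = character())
  write.csv(manifest, file.path(directory, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a cohort back from a WAV directory + manifest
#'
#' @param manifest Manifest data frame or path to a `manifest.csv`.
#' @param directory Directory holding the WAV files; defaults to the
#'   manifest's directory when `manifest` is a path.
#' @return A `ddk_cohort`.
#' @export
read_cohort <- function(manifest, directory = NULL) {
  if (is.character(manifest)) {
    if (is.null(directory)) directory <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(directory)) stop("directory must be given with a manifest data frame")
  needed <- c("file", "subject_id", "label", "task_id")
  if (!all(needed %in% names(manifest)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  bad <- setdiff(unique(manifest$label), c("PD", "HC"))
  if (length(bad)) stop("manifest contains unknown label(s): ",
                        paste(bad, collapse = ", "))
  # a subject must not appear under two labels
  lab_per_subj <- tapply(manifest$label, manifest$subject_id,
                         function(l) length(unique(l)))
  if (any(lab_per_subj > 1))
    stop("manifest label mismatch: subject(s) with conflicting labels: ",
         paste(names(lab_per_subj)[lab_per_subj > 1], collapse = ", "))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(directory, manifest$file[i])
    if (!file.exists(path)) stop("missing WAV file listed in manifest: ", path)
    w <- wav_read(path)
    audio_recording(w$samples, w$sample_rate, manifest$subject_id[i],
                    manifest$label[i], manifest$task_id[i])
  })
  structure(recs, class = "ddk_cohort")
}
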