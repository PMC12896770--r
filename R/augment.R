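# Data-augmentation operators. Two act on waveforms before the mel frontend
# (additive noise, circular time shift); five act on the 80x41 log-mel
# matrices (SpecAugment stripes, RandMasking blocks, RandMix block
# replacement, Cutting Masking cut-and-paste, Mixture Masking weighted
# blending). All operators preserve shape, keep untouched cells
# bit-identical, and have exact identity limits (alpha = 0, tau = 0, zero
# masks, identical source, lambda = 1). Block sources are always drawn from
# same-class items and labels are never mixed.

AUG_TECHNIQUES <- c("NOISE", "SHIFT", "SA", "RM", "RMI", "CM", "MM",
                    "WAVEFORM_COMBO")
WAVEFORM_TECHNIQUES <- c("NOISE", "SHIFT", "WAVEFORM_COMBO")
SOURCE_TECHNIQUES <- c("RMI", "CM", "MM")

#' Configuration of one augmentation operator
#'
#' Unset geometry arguments take technique-specific defaults: SpecAugment
#' uses one time mask (<= 8 frames) and one frequency mask (<= 12 bands);
#' RandMasking/RandMix use 3 blocks of <= 16 bands x 10 frames; Cutting and
#' Mixture Masking use a single region drawn up to the full 80 x 41 extent
#' (expected area about 26 % of the matrix). The operator magnitudes are
#' tunable because no canonical values exist for this task.
#'
#' @param technique One of `"NOISE"`, `"SHIFT"`, `"SA"`, `"RM"`, `"RMI"`,
#'   `"CM"`, `"MM"`, `"WAVEFORM_COMBO"`.
#' @param alpha Additive-noise intensity (linear amplitude of the standard
#'   Gaussian noise; waveforms are peak-normalized so 0.05 is 5 % of peak).
#' @param tau_fraction Circular time shift as a fraction of the waveform
#'   length, in `[0, 1)`.
#' @param n_time_masks,n_freq_masks SpecAugment stripe counts.
#' @param max_mask_frames,max_mask_bands SpecAugment maximum stripe widths;
#'   widths are drawn uniformly on `{0, ..., max}`.
#' @param n_blocks Number of rectangles for RandMasking / RandMix.
#' @param block_h,block_w Maximum block extents (mel bands / frames);
#'   heights and widths are drawn uniformly on `{1, ..., max}`.
#' @param lambda_mix Mixture-Masking weight on the target, in `[0, 1]`.
#' @param source_policy Block-source policy; only `"same_class"` exists.
#' @param fill_mode Mask fill: `"floor_db"` (-80) or `"matrix_mean"`.
#' @param seed Optional seed; when given, the operator draws from its own
#'   stream and leaves the caller's RNG untouched.
#' @return An `aug_config` object.
#' @export
aug_config <- function(technique,
                       alpha = 0.05,
                       tau_fraction = 0.1,
                       n_time_masks = 1L, n_freq_masks = 1L,
                       max_mask_frames = 8L, max_mask_bands = 12L,
                       n_blocks = NULL, block_h = NULL, block_w = NULL,
                       lambda_mix = 0.5,
                       source_policy = "same_class",
                       fill_mode = c("floor_db", "matrix_mean"),
                       seed = NULL) {
  technique <- match.arg(technique, AUG_TECHNIQUES)
  fill_mode <- match.arg(fill_mode)
  if (is.null(n_blocks)) n_blocks <- if (technique %in% c("CM", "MM")) 1L else 3L
  if (is.null(block_h)) block_h <- if (technique %in% c("CM", "MM")) 80L else 16L
  if (is.null(block_w)) block_w <- if (technique %in% c("CM", "MM")) 41L else 10L
  cfg <- list(technique = technique, alpha = alpha, tau_fraction = tau_fraction,
              n_time_masks = as.integer(n_time_masks),
              n_freq_masks = as.integer(n_freq_masks),
              max_mask_frames = as.integer(max_mask_frames),
              max_mask_bands = as.integer(max_mask_bands),
              n_blocks = as.integer(n_blocks),
              block_h = as.integer(block_h), block_w = as.integer(block_w),
              lambda_mix = lambda_mix,
              source_policy = match.arg(source_policy, "same_class"),
              fill_mode = fill_mode, seed = seed)
  if (cfg$alpha < 0) stop("aug_config: alpha must be >= 0")
  if (cfg$tau_fraction < 0 || cfg$tau_fraction >= 1)
    stop("aug_config: tau_fraction must lie in [0, 1)")
  if (cfg$max_mask_frames < 0 || cfg$max_mask_frames > 41L)
    stop("aug_config: max_mask_frames must lie in [0, 41]")
  if (cfg$max_mask_bands < 0 || cfg$max_mask_bands > 80L)
    stop("aug_config: max_mask_bands must lie in [0, 80]")
  if (cfg$n_time_masks < 0 || cfg$n_freq_masks < 0 || cfg$n_blocks < 0)
    stop("aug_config: mask/block counts must be >= 0")
  if (cfg$block_h < 1 || cfg$block_h > 80L)
    stop("aug_config: block_h must lie in [1, 80]")
  if (cfg$block_w < 1 || cfg$block_w > 41L)
    stop("aug_config: block_w must lie in [1, 41]")
  if (cfg$lambda_mix < 0 || cfg$lambda_mix > 1)
    stop("aug_config: lambda_mix must lie in [0, 1]")
  class(cfg) <- "aug_config"
  cfg
}

maybe_seeded <- function(cfg, code) {
  if (!is.null(cfg$seed)) with_seed(cfg$seed, code) else force(code)
}

check_spec_shape <- function(S, what = "spectrogram") {
  if (!is.matrix(S) || nrow(S) != 80L || ncol(S) != 41L)
    stop(what, " must be an 80x41 matrix")
  S
}

fill_value <- function(S, cfg) {
  if (cfg$fill_mode == "floor_db") .ddk$db_floor else mean(S)
}

#' Additive Gaussian noise (waveform level)
#'
#' `x' = x + alpha * n` with `n` i.i.d. standard Gaussian.
#' @param x Numeric waveform.
#' @param cfg An [aug_config()] (uses `alpha`, optionally `seed`).
#' @return Waveform of the same length.
#' @export
additive_noise <- function(x, cfg) {
  if (cfg$alpha == 0) return(x)
  maybe_seeded(cfg, x + cfg$alpha * rnorm(length(x)))
}

#' Circular time shift (waveform level)
#'
#' Shifts by `tau = round(tau_fraction * length(x))` samples with circular
#' boundary handling, preserving the multiset of sample values.
#' @param x Numeric waveform.
#' @param cfg An [aug_config()] (uses `tau_fraction`).
#' @return Waveform of the same length.
#' @export
time_shift <- function(x, cfg) {
  n <- length(x)
  tau <- round(cfg$tau_fraction * n) %% n
  if (tau == 0) return(x)
  c(x[(n - tau + 1L):n], x[1:(n - tau)])
}

# draw a stripe of width on {0..maxw} over an axis of length len;
# returns NULL (no-op) or c(start, width)
draw_stripe <- function(len, maxw) {
  w <- sample.int(maxw + 1L, 1L) - 1L
  if (w == 0L) return(NULL)
  c(sample.int(len - w + 1L, 1L), w)
}

# draw a block up to bh x bw within 80 x 41; returns c(r0, h, c0, w)
draw_block <- function(bh, bw) {
  h <- sample.int(bh, 1L)
  w <- sample.int(bw, 1L)
  c(sample.int(80L - h + 1L, 1L), h, sample.int(41L - w + 1L, 1L), w)
}

#' SpecAugment: axis-spanning time and frequency stripes
#'
#' Applies `n_time_masks` frame stripes (all 80 bands) and `n_freq_masks`
#' band stripes (all 41 frames); stripe widths are drawn uniformly on
#' `{0, ..., max}`, so a stripe may be empty. Masked cells are set to the
#' fill value; all other cells are bit-identical to the input.
#' @param S 80x41 mel matrix.
#' @param cfg An [aug_config()].
#' @return Masked 80x41 matrix.
#' @export
spec_augment <- function(S, cfg) {
  check_spec_shape(S)
  fill <- fill_value(S, cfg)
  maybe_seeded(cfg, {
    for (i in seq_len(cfg$n_time_masks)) {
      st <- draw_stripe(41L, cfg$max_mask_frames)
      if (!is.null(st)) S[, st[1]:(st[1] + st[2] - 1L)] <- fill
    }
    for (i in seq_len(cfg$n_freq_masks)) {
      st <- draw_stripe(80L, cfg$max_mask_bands)
      if (!is.null(st)) S[st[1]:(st[1] + st[2] - 1L), ] <- fill
    }
    S
  })
}

#' RandMasking: multiple randomly placed rectangular masks
#'
#' `n_blocks` rectangles with heights on `{1..block_h}` and widths on
#' `{1..block_w}`, positions uniform, overlaps allowed; masked cells take
#' the fill value.
#' @inheritParams spec_augment
#' @return Masked 80x41 matrix.
#' @export
rand_masking <- function(S, cfg) {
  check_spec_shape(S)
  fill <- fill_value(S, cfg)
  maybe_seeded(cfg, {
    for (i in seq_len(cfg$n_blocks)) {
      b <- draw_block(cfg$block_h, cfg$block_w)
      S[b[1]:(b[1] + b[2] - 1L), b[3]:(b[3] + b[4] - 1L)] <- fill
    }
    S
  })
}

#' RandMix: replace random blocks with aligned blocks of another sample
#'
#' @param S_target,S_source 80x41 mel matrices; the source is normally a
#'   same-class sample from the current batch.
#' @param cfg An [aug_config()].
#' @return 80x41 matrix equal to the target outside the blocks and to the
#'   source (same coordinates) inside them.
#' @export
rand_mix <- function(S_target, S_source, cfg) {
  check_spec_shape(S_target, "target")
  check_spec_shape(S_source, "source")
  maybe_seeded(cfg, {
    for (i in seq_len(cfg$n_blocks)) {
      b <- draw_block(cfg$block_h, cfg$block_w)
      rows <- b[1]:(b[1] + b[2] - 1L); cols <- b[3]:(b[3] + b[4] - 1L)
      S_target[rows, cols] <- S_source[rows, cols]
    }
    S_target
  })
}

#' Cutting Masking: cut-and-paste of one contiguous region
#'
#' A single rectangle (height on `{1..block_h}`, width on `{1..block_w}`,
#' position uniform) is replaced by the corresponding region of the source
#' sample; the label of the output is the label of the target.
#' @inheritParams rand_mix
#' @return 80x41 matrix.
#' @export
cut_masking <- function(S_target, S_source, cfg) {
  check_spec_shape(S_target, "target")
  check_spec_shape(S_source, "source")
  maybe_seeded(cfg, {
    b <- draw_block(cfg$block_h, cfg$block_w)
    rows <- b[1]:(b[1] + b[2] - 1L); cols <- b[3]:(b[3] + b[4] - 1L)
    S_target[rows, cols] <- S_source[rows, cols]
    S_target
  })
}

#' Mixture Masking: weighted blending of one region
#'
#' Inside the drawn region the output is
#' `lambda * target + (1 - lambda) * source`; outside, the target is
#' unchanged.
#' @inheritParams rand_mix
#' @return 80x41 matrix.
#' @export
mixture_masking <- function(S_target, S_source, cfg) {
  check_spec_shape(S_target, "target")
  check_spec_shape(S_source, "source")
  if (cfg$lambda_mix < 0 || cfg$lambda_mix > 1)
    stop("lambda_mix must lie in [0, 1]")
  maybe_seeded(cfg, {
    b <- draw_block(cfg$block_h, cfg$block_w)
    rows <- b[1]:(b[1] + b[2] - 1L); cols <- b[3]:(b[3] + b[4] - 1L)
    S_target[rows, cols] <- cfg$lambda_mix * S_target[rows, cols] +
      (1 - cfg$lambda_mix) * S_source[rows, cols]
    S_target
  })
}

apply_spec_op <- function(S, src, cfg) {
  switch(cfg$technique,
         SA = spec_augment(S, cfg),
         RM = rand_masking(S, cfg),
         RMI = rand_mix(S, src, cfg),
         CM = cut_masking(S, src, cfg),
         MM = mixture_masking(S, src, cfg),
         stop("not a spectrogram-level technique: ", cfg$technique))
}

apply_wave_op <- function(x, cfg) {
  switch(cfg$technique,
         NOISE = additive_noise(x, cfg),
         SHIFT = time_shift(x, cfg),
         WAVEFORM_COMBO = time_shift(additive_noise(x, cfg), cfg),
         stop("not a waveform-level technique: ", cfg$technique))
}

#' Symmetric dataset doubling by augmentation
#'
#' Returns the originals plus exactly one augmented copy per original, so
#' the output holds `2n` items with class balance preserved. Techniques in
#' `cfgs` are composed in the listed order; waveform-level operators are
#' applied to the segment waveform before the mel frontend, spectrogram
#' operators afterwards. Block sources are drawn uniformly from same-class
#' items of the dataset (excluding the item itself); an item whose class has
#' no other member passes through unaugmented (with a message).
#'
#' This must only ever be applied to training partitions: the `meta` of the
#' copies records the source subjects so leakage can be audited.
#'
#' @param dataset A `ddk_dataset` (see [prepare_dataset()]).
#' @param cfgs One [aug_config()] or a list of them, composed in order.
#' @param seed Seed for all augmentation draws (one stream, split per item).
#' @return A `ddk_dataset` with `2n` spectrograms; copies are flagged in
#'   `meta$augmented` and carry `meta$source_subject`.
#' @export
expand_training_set <- function(dataset, cfgs, seed = 1L) {
  if (inherits(cfgs, "aug_config")) cfgs <- list(cfgs)
  stopifnot(all(vapply(cfgs, inherits, logical(1), "aug_config")))
  # item-level streams own the randomness; per-operator seeds are ignored here
  cfgs <- lapply(cfgs, function(cf) { cf$seed <- NULL; cf })
  wave_cfgs <- Filter(function(cf) cf$technique %in% WAVEFORM_TECHNIQUES, cfgs)
  spec_cfgs <- Filter(function(cf) !cf$technique %in% WAVEFORM_TECHNIQUES, cfgs)
  n <- dim(dataset$spec)[3]
  if (n == 0) return(dataset)
  if (length(wave_cfgs) > 0 && is.null(dataset$segments))
    stop("waveform-level augmentation needs the segment waveforms")
  needs_src <- any(vapply(spec_cfgs, function(cf)
    cf$technique %in% SOURCE_TECHNIQUES, logical(1)))
  fb <- mel_filterbank()
  labels <- dataset$meta$label
  aug <- array(0, dim = dim(dataset$spec))
  src_subj <- character(n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(seed, i), {
      pool <- which(labels == labels[i])
      pool <- pool[pool != i]
      if (needs_src && length(pool) == 0) {
        message("no same-class source for item ", i, "; passed through unaugmented")
        aug[, , i] <- dataset$spec[, , i]
        src_subj[i] <- dataset$meta$subject_id[i]
      } else {
        if (length(wave_cfgs) > 0) {
          w <- dataset$segments[, i]
          for (cf in wave_cfgs) w <- apply_wave_op(w, cf)
          S <- unclass(compute_melspec(w, fb))
        } else {
          S <- dataset$spec[, , i]
        }
        j <- if (needs_src) pool[sample.int(length(pool), 1L)] else i
        src <- if (needs_src) dataset$spec[, , j] else NULL
        for (cf in spec_cfgs) S <- apply_spec_op(S, src, cf)
        aug[, , i] <- S
        src_subj[i] <- if (needs_src) dataset$meta$subject_id[j]
                       else dataset$meta$subject_id[i]
      }
    })
  }
  meta_orig <- dataset$meta
  meta_orig$augmented <- FALSE
  meta_orig$source_subject <- dataset$meta$subject_id
  meta_aug <- dataset$meta
  meta_aug$augmented <- TRUE
  meta_aug$source_subject <- src_subj
  out_spec <- array(0, dim = c(80L, 41L, 2L * n))
  out_spec[, , seq_len(n)] <- dataset$spec
  out_spec[, , n + seq_len(n)] <- aug
  structure(list(segments = NULL, spec = out_spec,
                 meta = rbind(meta_orig, meta_aug)),
            class = "ddk_dataset")
}
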