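# Augmentation operators: exact identity limits, formula-forced examples,
# partition properties, Monte-Carlo geometry checks, dataset doubling.

rand_spec <- function(seed = 1) {
  set.seed(seed)
  matrix(runif(80 * 41, -60, -10), 80, 41)
}

test_that("additive noise follows x + alpha * n and its identity limit", {
  x <- c(1, 0, -1)
  expect_identical(additive_noise(x, aug_config("NOISE", alpha = 0)), x)
  out <- additive_noise(x, aug_config("NOISE", alpha = 0.1, seed = 4L))
  n_drawn <- ddkcnn:::with_seed(4L, rnorm(3))
  expect_equal(out, x + 0.1 * n_drawn)
  # the forced-formula example: with n = (1, 1, 1), x' = (1.1, 0.1, -0.9)
  expect_equal(c(1, 0, -1) + 0.1 * c(1, 1, 1), c(1.1, 0.1, -0.9))
})

test_that("additive noise at alpha 0.1 on a unit-power signal gives ~20 dB SNR", {
  t <- (0:15999) / 16000
  x <- sqrt(2) * sin(2 * pi * 440 * t) # unit power
  out <- additive_noise(x, aug_config("NOISE", alpha = 0.1, seed = 2L))
  snr <- 10 * log10(mean(x^2) / mean((out - x)^2))
  expect_lt(abs(snr - 20), 1)
})

test_that("time shift is circular, value preserving, and locatable by cross-correlation", {
  x <- rnorm(512)
  expect_identical(time_shift(x, aug_config("SHIFT", tau_fraction = 0)), x)
  # shift by the full length is the identity (circularity)
  n <- 100
  expect_identical(time_shift(x[1:n], aug_config("SHIFT", tau_fraction = 0.999)),
                   x[1:n])
  cfg <- aug_config("SHIFT", tau_fraction = 0.25)
  y <- time_shift(x, cfg)
  expect_identical(sort(y), sort(x))
  # circular cross-correlation argmax at lag tau
  cc <- vapply(0:511, function(lag)
    sum(y * x[((seq_len(512) - 1 - lag) %% 512) + 1]), numeric(1))
  expect_equal(which.max(cc) - 1, round(0.25 * 512))
})

test_that("masking operators are exact identities in their zero limits", {
  S <- rand_spec()
  expect_identical(spec_augment(S, aug_config("SA", n_time_masks = 0,
                                              n_freq_masks = 0)), S)
  expect_identical(rand_masking(S, aug_config("RM", n_blocks = 0)), S)
  expect_identical(rand_mix(S, S, aug_config("RMI")), S)
  expect_identical(cut_masking(S, S, aug_config("CM")), S)
  expect_identical(mixture_masking(S, rand_spec(2),
                                   aug_config("MM", lambda_mix = 1)), S)
})

test_that("SpecAugment stripes span a full axis and fill with the configured value", {
  S <- rand_spec()
  cfg <- aug_config("SA", n_time_masks = 0, n_freq_masks = 1,
                    max_mask_bands = 12, seed = 10L)
  out <- spec_augment(S, cfg)
  changed_rows <- which(rowSums(out != S) > 0)
  k <- length(changed_rows)
  expect_lte(k, 12)
  if (k > 0) {
    expect_equal(sum(out != S), 41 * k)           # full-width stripes
    expect_equal(changed_rows, seq(min(changed_rows), max(changed_rows)))
    expect_true(all(out[out != S] == -80))
  }
  # matrix-mean fill mode
  cfgm <- aug_config("SA", n_time_masks = 1, n_freq_masks = 0,
                     fill_mode = "matrix_mean", seed = 11L)
  outm <- spec_augment(S, cfgm)
  expect_true(all(outm[outm != S] == mean(S)))
  expect_error(aug_config("SA", max_mask_bands = 90), "max_mask_bands")
})

test_that("SpecAugment masked fraction matches the uniform-width mean", {
  cfg <- aug_config("SA", n_time_masks = 1, n_freq_masks = 0,
                    max_mask_frames = 8)
  S <- rand_spec()
  set.seed(123)
  frac <- mean(vapply(seq_len(10000), function(i)
    mean(spec_augment(S, cfg) != S), numeric(1)))
  expect_lt(abs(frac - (8 / 2) / 41), 0.01) # E[width]/frames for width ~ U{0..8}
})

test_that("RandMasking changes at most the summed block area, all to the fill", {
  S <- rand_spec()
  cfg <- aug_config("RM", n_blocks = 3, block_h = 16, block_w = 10, seed = 5L)
  out <- rand_masking(S, cfg)
  expect_true(all(out[out != S] == -80))
  expect_lte(sum(out != S), 3 * 16 * 10)
  expect_gt(sum(out != S), 0)
})

test_that("block replacement is a partition between target and source", {
  S <- rand_spec(1)
  R <- rand_spec(2)
  for (f in list(function() rand_mix(S, R, aug_config("RMI", seed = 6L)),
                 function() cut_masking(S, R, aug_config("CM", seed = 7L)))) {
    out <- f()
    expect_true(all(out == S | out == R))
    expect_gt(sum(out == R & out != S), 0)
  }
  # a full 80x41 draw replaces everything
  full <- rand_mix(S, R, aug_config("RMI", n_blocks = 1, block_h = 80,
                                    block_w = 41, seed = 1743L))
  expect_identical(full, R)
})

test_that("cut region area matches its configured expected fraction", {
  cfg <- aug_config("CM") # block up to 80x41, E[area] = 40.5 * 21 cells
  S <- rand_spec(1)
  R <- S + 1 # every cell differs, so changed cells = region area
  set.seed(321)
  frac <- mean(vapply(seq_len(10000), function(i)
    sum(cut_masking(S, R, cfg) != S) / 3280, numeric(1)))
  expect_lt(abs(frac - (40.5 * 21) / 3280), 0.01)
})

test_that("mixture masking blends exactly with weight lambda", {
  S <- rand_spec(1)
  R <- rand_spec(2)
  out0 <- mixture_masking(S, R, aug_config("MM", lambda_mix = 0, seed = 8L))
  region <- out0 != S
  expect_true(all(out0[region] == R[region]))
  out5 <- mixture_masking(S, R, aug_config("MM", lambda_mix = 0.5, seed = 8L))
  expect_equal(out5[region], (S[region] + R[region]) / 2)
  expect_identical(out5[!region], S[!region])
  expect_error(aug_config("MM", lambda_mix = 1.5), "lambda_mix")
})

test_that("seeded operators are reproducible", {
  S <- rand_spec()
  cfg <- aug_config("RM", seed = 99L)
  expect_identical(rand_masking(S, cfg), rand_masking(S, cfg))
})

test_that("dataset doubling yields 2n items with class balance preserved", {
  ds <- make_tiny_dataset(10) # 5 PD / 5 HC
  out <- expand_training_set(ds, aug_config("CM"), seed = 1L)
  expect_equal(dim(out$spec)[3], 20)
  expect_equal(as.integer(table(out$meta$label)), c(10L, 10L))
  expect_equal(sum(out$meta$augmented), 10)
  # originals pass through bit-identically
  expect_identical(out$spec[, , 1:10], ds$spec)
  # augmented copies keep the label of their target
  expect_identical(out$meta$label[11:20], ds$meta$label)
  # sources are same-class items
  src_lab <- ds$meta$label[match(out$meta$source_subject[11:20],
                                 ds$meta$subject_id)]
  expect_identical(src_lab, ds$meta$label)
  # empty input
  empty <- make_tiny_dataset(0)
  expect_equal(dim(expand_training_set(empty, aug_config("CM"))$spec)[3], 0)
})

test_that("composed augmentation (CM then SA) is deterministic under a seed", {
  ds <- make_tiny_dataset(6)
  cfgs <- list(aug_config("CM"), aug_config("SA"))
  a <- expand_training_set(ds, cfgs, seed = 3L)
  b <- expand_training_set(ds, cfgs, seed = 3L)
  expect_identical(a$spec, b$spec)
  c2 <- expand_training_set(ds, cfgs, seed = 4L)
  expect_false(identical(a$spec, c2$spec))
})

test_that("waveform-level doubling recomputes spectrograms of perturbed audio", {
  ds <- make_tiny_dataset(4, with_segments = TRUE)
  # tiny-amplitude segments need consistent spectrograms for the originals
  ds$spec <- batch_melspec(ds$segments)$spec
  out <- expand_training_set(ds, aug_config("WAVEFORM_COMBO", alpha = 0.05,
                                            tau_fraction = 0.1), seed = 2L)
  expect_equal(dim(out$spec)[3], 8)
  expect_false(identical(out$spec[, , 5], out$spec[, , 1]))
  expect_equal(max(out$spec[, , 5]), 0) # still a valid referenced dB matrix
})

test_that("an item without a same-class source passes through unaugmented", {
  ds <- make_tiny_dataset(2) # one PD, one HC
  expect_message(out <- expand_training_set(ds, aug_config("CM"), seed = 1L),
                 "passed through")
  expect_identical(out$spec[, , 3], ds$spec[, , 1])
  expect_identical(out$spec[, , 4], ds$spec[, , 2])
})
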