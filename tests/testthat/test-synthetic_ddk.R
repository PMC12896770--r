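# Synthetic DDK cohort generator: determinism, pulse-train structure,
# class-effect monotonicity, WAV round trips.

small_spec <- function(...) {
  cohort_spec(n_subjects_per_class = 2L, recordings_per_subject = 1L,
              duration_s = 1, seed = 7L, ...)
}

test_that("identical spec and seed give a bit-identical cohort", {
  a <- generate_cohort(small_spec())
  b <- generate_cohort(small_spec())
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
})

test_that("enlarging the cohort does not reshuffle existing subjects", {
  a <- generate_cohort(small_spec())
  b <- generate_cohort(cohort_spec(n_subjects_per_class = 4L,
                                   recordings_per_subject = 1L,
                                   duration_s = 1, seed = 7L))
  ids_a <- vapply(a, `[[`, character(1), "subject_id")
  ids_b <- vapply(b, `[[`, character(1), "subject_id")
  for (id in ids_a)
    expect_identical(a[[match(id, ids_a)]]$samples,
                     b[[match(id, ids_b)]]$samples)
})

test_that("cohort structure matches the requested counts and labeling", {
  spec <- cohort_spec(n_subjects_per_class = 3L, recordings_per_subject = 2L,
                      duration_s = 1, seed = 1L)
  co <- generate_cohort(spec)
  expect_length(co, 3 * 2 * 2)
  ids <- vapply(co, `[[`, character(1), "subject_id")
  labs <- vapply(co, `[[`, character(1), "label")
  expect_equal(length(unique(ids)), 6)
  # each subject keeps one label across recordings
  expect_true(all(tapply(labs, ids, function(l) length(unique(l))) == 1))
  # sample count within one sample of duration * rate
  expect_true(all(vapply(co, function(r)
    abs(length(r$samples) - spec$duration_s * spec$sample_rate) <= 1,
    logical(1))))
})

test_that("envelope-peak oracle counts about rate * duration syllables", {
  sp <- cohort_spec(n_subjects_per_class = 3L, recordings_per_subject = 1L,
                    duration_s = 2, hc_syllable_rate = 5, subject_sd = 0,
                    pd_rate_deficit = 0.5, seed = 3L)
  co <- generate_cohort(sp)
  hc <- Filter(function(r) r$label == "HC", co)
  counts <- vapply(hc, function(r) count_envelope_peaks(r$samples), integer(1))
  expect_true(all(counts >= 9 & counts <= 11))
})

test_that("increasing the rate deficit decreases mean PD peak count", {
  mean_pd_peaks <- function(deficit) {
    sp <- cohort_spec(n_subjects_per_class = 20L, recordings_per_subject = 1L,
                      duration_s = 2, pd_rate_deficit = deficit,
                      subject_sd = 0.2, seed = 99L)
    co <- generate_cohort(sp)
    pd <- Filter(function(r) r$label == "PD", co)
    mean(vapply(pd, function(r) count_envelope_peaks(r$samples), integer(1)))
  }
  m <- vapply(c(0, 1, 2), mean_pd_peaks, numeric(1))
  expect_true(m[1] > m[2])
  expect_true(m[2] > m[3])
})

test_that("zero deficits make the class distributions identical", {
  sp <- cohort_spec(n_subjects_per_class = 5L, recordings_per_subject = 1L,
                    duration_s = 1, pd_rate_deficit = 0,
                    pd_mod_depth_deficit = 0, pd_noise_excess = 0, seed = 5L)
  co <- generate_cohort(sp)
  by_lab <- split(co, vapply(co, `[[`, character(1), "label"))
  # HC subject i and PD subject i use different substreams, so equality is
  # distributional, not pathwise; compare summary statistics instead
  stat <- function(recs) {
    x <- vapply(recs, function(r) c(stats::sd(r$samples),
                                    mean(abs(r$samples))), numeric(2))
    rowMeans(x)
  }
  s_hc <- stat(by_lab$HC)
  s_pd <- stat(by_lab$PD)
  expect_lt(max(abs(s_hc - s_pd) / s_hc), 0.25)
})

test_that("invalid cohort parameters are rejected naming the field", {
  expect_error(cohort_spec(duration_s = 0), "duration_s")
  expect_error(cohort_spec(pd_rate_deficit = 10), "pd_rate_deficit")
  expect_error(cohort_spec(pd_mod_depth_deficit = 0.95), "pd_mod_depth_deficit")
  expect_error(cohort_spec(hc_mod_depth = 1.4), "hc_mod_depth")
  expect_error(cohort_spec(pd_noise_excess = -0.1), "pd_noise_excess")
})

test_that("WAV round trip is exact to 16-bit quantization", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  manifest <- write_cohort_wav(co, dir)
  expect_setequal(names(manifest), c("file", "subject_id", "label", "task_id"))
  back <- read_cohort(file.path(dir, "manifest.csv"))
  expect_length(back, length(co))
  for (i in seq_along(co)) {
    expect_identical(back[[i]]$subject_id, co[[i]]$subject_id)
    expect_identical(back[[i]]$label, co[[i]]$label)
    expect_lte(max(abs(back[[i]]$samples - co[[i]]$samples)), 2^-15)
  }
})

test_that("empty cohort writes an empty manifest", {
  dir <- withr::local_tempdir()
  manifest <- write_cohort_wav(structure(list(), class = "ddk_cohort"), dir)
  expect_equal(nrow(manifest), 0)
})

test_that("manifest validation rejects bad labels and missing files", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  manifest <- write_cohort_wav(co, dir)
  bad <- manifest
  bad$label[1] <- "PARKINSON"
  expect_error(read_cohort(bad, dir), "unknown label")
  gone <- manifest
  gone$file[1] <- "nonexistent.wav"
  expect_error(read_cohort(gone, dir), "missing WAV")
  conflict <- rbind(manifest, manifest[1, ])
  conflict$label[nrow(conflict)] <- setdiff(c("PD", "HC"), conflict$label[1])
  expect_error(read_cohort(conflict, dir), "conflicting labels")
})
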