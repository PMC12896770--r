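#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Two synthetic DDK cohorts stand in for the restricted clinical corpora:
# a 50 PD + 50 HC training/validation cohort (two DDK takes per subject)
# and an independent 20 PD + 20 HC test cohort recorded "elsewhere" (one
# take per subject, its own seed, so subjects and noise draws are disjoint).
# Outputs: PCM-16 WAV files + manifest.csv per cohort under results/.

library(ddkcnn)

out_root <- "results/cohorts"
train_spec <- cohort_spec(n_subjects_per_class = 50L,
                          recordings_per_subject = 2L,
                          duration_s = 3, seed = 101L)
test_spec <- cohort_spec(n_subjects_per_class = 20L,
                         recordings_per_subject = 1L,
                         duration_s = 3, seed = 202L)

message("generating training cohort (", 2 * train_spec$n_subjects_per_class,
        " subjects) ...")
train <- generate_cohort(train_spec)
m1 <- write_cohort_wav(train, file.path(out_root, "train"))

message("generating independent test cohort (",
        2 * test_spec$n_subjects_per_class, " subjects) ...")
test <- generate_cohort(test_spec)
m2 <- write_cohort_wav(test, file.path(out_root, "test"))

message("wrote ", nrow(m1), " training and ", nrow(m2),
        " test recordings under ", out_root)
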