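#!/usr/bin/env Rscript
# Stage 2: standardize and featurize.
#
# Reads the WAV cohorts of stage 1, runs the frontend (peak normalization,
# mono, 16 kHz, 160 ms / 50 % segmentation, 80x41 log-mel), and caches the
# model-ready datasets as RDS under results/features/. The cache is purely
# a convenience for stages 3-4; everything can be recomputed from the WAVs.

library(ddkcnn)

in_root <- "results/cohorts"
out_root <- "results/features"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

for (role in c("train", "test")) {
  cohort <- read_cohort(file.path(in_root, role, "manifest.csv"))
  ds <- prepare_dataset(cohort)
  if (role == "test") # structural disjointness from the training cohort
    ds$meta$subject_id <- paste0("T-", ds$meta$subject_id)
  saveRDS(ds, file.path(out_root, paste0(role, ".rds")))
  message(role, ": ", dim(ds$spec)[3], " segments of ",
          paste(dim(ds$spec)[1:2], collapse = "x"), " from ",
          nrow(dataset_subjects(ds)), " subjects")
}
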