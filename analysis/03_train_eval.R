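#!/usr/bin/env Rscript
# Stage 3: train and evaluate every (strategy x augmentation method) cell.
#
# Methods: baseline (no augmentation), Cutting Masking, and the CM + SA
# combination. Strategies: train-100%, holdout 70/30, and five-fold
# subject-independent CV with best-model and mean-model selection; the
# selected model of each cell is evaluated on the independent test cohort.
# Expect roughly 10-15 minutes on one CPU at the stage-1 cohort sizes.

library(ddkcnn)

train_ds <- readRDS("results/features/train.rds")
test_ds <- readRDS("results/features/test.rds")

mc <- model_config(n_conv_layers = 4L)
tc <- train_config(lr = 1e-3, batch_size = 64L, max_epochs = 20L,
                   patience = 6L)
methods <- list(
  baseline = NULL,
  CM = aug_config("CM"),
  `CM+SA` = list(aug_config("CM"), aug_config("SA")))

results <- list()
cell <- 0L
for (strategy in c("train100", "holdout", "cv_best", "cv_mean")) {
  for (mname in names(methods)) {
    cell <- cell + 1L
    tc_cell <- tc
    tc_cell$seed <- ddkcnn:::derive_seed(1L, cell)
    message("[", strategy, " / ", mname, "]")
    res <- ddkcnn:::run_cell(strategy, train_ds, test_ds, mc, tc_cell,
                             methods[[mname]])
    res$method <- mname
    message("  test accuracy: ", round(res$metrics[["accuracy"]], 3),
            if (!is.null(res$cv_accuracy))
              paste0("  (pooled CV accuracy: ", round(res$cv_accuracy, 3), ")")
            else "")
    results[[paste(strategy, mname, sep = "/")]] <- res
  }
}
saveRDS(results, "results/eval_results.rds")
write_report(render_report(results), "results/results.tsv")
message("wrote results/results.tsv (", length(results), " cells)")
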