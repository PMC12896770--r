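#!/usr/bin/env Rscript
# Stage 4: tabulate.
#
# Prints the independent-test result table of stage 3 (one row per
# strategy x method, metrics rounded half-up to two decimals) and, for the
# CV strategies, the across-fold validation mean +- SD.

library(ddkcnn)

results <- readRDS("results/eval_results.rds")
report <- render_report(results)
print(report, row.names = FALSE)

cat("\nAcross-fold validation summaries (CV cells):\n")
for (name in names(results)) {
  r <- results[[name]]
  if (is.null(r$fold_summary)) next
  s <- r$fold_summary
  cat(sprintf("  %-18s acc %.2f±%.2f  (selected fold %d)\n", name,
              s$mean[s$metric == "accuracy"], s$sd[s$metric == "accuracy"],
              r$selected_fold))
}
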