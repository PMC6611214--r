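#!/usr/bin/env Rscript

# Re-evaluates the packaged published single-item ERP summary table: applies
# discrimination criterion 1 to the six most-preferred products and
# criterion 2 to the six least-preferred ones, in each of the six time
# windows, using the printed means and FDR significance flags.
#
# Finding: 51 of the 72 item x window cells fulfil their criterion (70.8%).
# The N200 column discriminates at chance (6/12), while the late windows do
# substantially better (8 to 10 of 12); pooling the four windows spanning
# 800-3000 ms gives 37/48 (77.1%). Dropping the two median-split boundary
# items (ranks 6 and 7) moves the overall rate only to 43/60 (71.7%).

library(sierp)

out_dir <- "results/published"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ev <- evaluate_published_table()
acc <- ev$accuracy

grid <- data.frame(rank = rownames(ev$verdicts), ev$verdicts,
                   check.names = FALSE)
write.csv(grid, file.path(out_dir, "verdict_grid.csv"), row.names = FALSE)

summary <- list(
  overall = c(acc$n_true, acc$n_total),
  percent_overall = 100 * acc$overall,
  by_window_true = as.list(acc$by_window_true),
  percent_psw_800_3000 = 100 * acc$psw_800_3000,
  percent_excluding_boundary = 100 * acc$excluding,
  fdr_flag_agreement = ev$fdr_diagnostic
)
jsonlite::write_json(summary, file.path(out_dir, "accuracies.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("overall: %d/%d (%.1f%%)\n", acc$n_true, acc$n_total,
            100 * acc$overall))
print(acc$by_window_true)
cat(sprintf("PSW 800-3000 pooled: %.1f%%\n", 100 * acc$psw_800_3000))
cat(sprintf("excluding boundary ranks 6 and 7: %d/%d (%.1f%%)\n",
            acc$excluding_true, acc$excluding_total, 100 * acc$excluding))
cat(sprintf("BH re-run on printed p-values agrees with %d/%d flags (single family), %d/%d (per window)\n",
            ev$fdr_diagnostic$agree_all, ev$fdr_diagnostic$n_flags,
            ev$fdr_diagnostic$agree_per_window, ev$fdr_diagnostic$n_flags))
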