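#!/usr/bin/env Rscript
# Leave-one-out evaluation of the age-regression pipeline on every
# dataset variant produced by 02_extract_features.R: per-fold Spearman
# top-15 selection, PCA to 3 components, two-hidden-layer perceptron.
# Writes per-variant prediction files and a summary metrics table
# (results/metrics.csv) in the layout of the study's result tables:
# one row per data variant, columns R2 / RMSE / MSE / MAE.

library(bonetex)

seed <- 42L
feat_dir <- "results/features"
out_dir <- "results/loo"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (roi in c("bone", "growth")) {
  for (mod in c("t1", "t2")) {
    for (enc in c("dicom", "png")) {
      f <- file.path(feat_dir, sprintf("%s_%s_%s.csv", roi, mod, enc))
      tab <- read_feature_csv(f)
      rep <- loo_evaluate(tab, pipeline_config(seed = seed))
      write_report(rep,
                   file.path(out_dir, sprintf("%s_%s_%s_pred.csv", roi, mod, enc)),
                   file.path(out_dir, sprintf("%s_%s_%s_metrics.json", roi, mod, enc)))
      m <- rep$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        region = roi, data = sprintf("%s %s-weighted", toupper(enc), toupper(mod)),
        n = nrow(tab$features), R2 = round(m$r2, 4), RMSE = round(m$rmse, 4),
        MSE = round(m$mse, 4), MAE = round(m$mae, 4))
      cat(sprintf("  %-7s %-16s n=%2d  R2=%.4f RMSE=%.4f MSE=%.4f MAE=%.4f\n",
                  roi, sprintf("%s %s", toupper(enc), toupper(mod)),
                  nrow(tab$features), m$r2, m$rmse, m$mse, m$mae))
    }
  }
}
metrics <- do.call(rbind, rows)
utils::write.csv(metrics, "results/metrics.csv", row.names = FALSE)
cat("Wrote results/metrics.csv\n")
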