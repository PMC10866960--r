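#!/usr/bin/env Rscript
# Stage 5: feature importance and single-feature reports (Q2).
#
# Re-runs the best configuration (RECIST sphere, no inter-feature
# filter, volume filter on), aggregates the per-iteration forest
# importances (per-iteration min-max normalization, filtered features
# zeroed, averaged, re-normalized), and for every feature above the 0.80
# importance threshold reports its biserial correlation with the
# outcome and its single-feature ROC (Table-3-shaped). Also reports the
# size-vs-outcome correlations (ROI volume and RECIST length).
#
#   Rscript analysis/05_feature_analysis.R [--iterations 100] [--seed 1]
#     [--roi sphere_recist] [--features results] [--out results]

suppressMessages({ library(optparse); library(sabradiomics) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--iterations", type = "integer", default = 100L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--roi", type = "character", default = "sphere_recist"),
  make_option("--features", type = "character", default = "results"),
  make_option("--out", type = "character", default = "results")
)))

ft <- read_feature_table(file.path(opts$features,
                                   sprintf("features_%s.csv", opts$roi)))
res <- run_experiment(ft, experiment_config(
  n_iterations = opts$iterations, inter_corr_filter = FALSE,
  volume_filter = TRUE, seed = opts$seed
))
agg <- aggregate_importance(res$importance, kept = res$kept)
cat(sprintf("model AUC %.3f [%.3f, %.3f]; %d features above the 0.80 importance threshold\n",
            res$auc[["mean"]], res$auc[["lo"]], res$auc[["hi"]], length(agg$top)))

rows <- lapply(agg$top, function(f) {
  row <- single_feature_roc(ft$features[, f], ft$labels, name = f)
  row$importance <- agg$scores[[f]]
  row
})
tab3 <- do.call(rbind, rows)
tab3 <- tab3[order(-tab3$importance), ]
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
utils::write.csv(tab3, file.path(opts$out, "table3_top_features.csv"),
                 row.names = FALSE)
for (i in seq_len(nrow(tab3))) {
  cat(sprintf("%-44s r=%+.2f p=%.3g AUC %.2f sens %.0f%% spec %.0f%%%s\n",
              tab3$feature[i], tab3$r[i], tab3$p[i], tab3$auc[i],
              100 * tab3$sensitivity[i], 100 * tab3$specificity[i],
              ifelse(tab3$flipped[i], " (outcomes flipped)", "")))
}

vol_cor <- biserial(ft$volumes, ft$labels)
cat(sprintf("\nROI volume vs outcome: r = %.3f, p = %.2g (%s)\n",
            vol_cor$r, vol_cor$p, vol_cor$type))
len_cor <- NULL
ann_path <- file.path(opts$features, "cohort", "annotations.csv")
if (file.exists(ann_path)) {
  ann <- utils::read.csv(ann_path)
  pd <- ann[ann$scan_index == ann$pd_scan, ]
  pd <- pd[match(ft$case_ids, pd$case_id), ]
  len_cor <- biserial(pd$length_mm, ft$labels)
  cat(sprintf("RECIST length vs outcome: r = %.3f, p = %.2g (%s)\n",
              len_cor$r, len_cor$p, len_cor$type))
}
jsonlite::write_json(
  list(auc = as.list(res$auc), n_top = length(agg$top),
       volume_outcome = vol_cor, recist_length_outcome = len_cor,
       importance = as.list(sort(agg$scores[agg$scores > 0.5], decreasing = TRUE))),
  file.path(opts$out, "q2_feature_analysis.json"), auto_unbox = TRUE, digits = NA
)
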