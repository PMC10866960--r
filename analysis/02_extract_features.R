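#!/usr/bin/env Rscript
# Stage 2: build the six ROIs and extract radiomic features.
#
# Regenerates the cohort deterministically from the seed, resamples
# every progressive-disease scan to the common 0.74 x 0.74 x 5.00 mm
# grid when needed, builds each requested ROI from its RECIST line, and
# writes one cases-x-features CSV per ROI kind (180 features; 384 for
# the solid+GGO pair).
#
#   Rscript analysis/02_extract_features.R [--n 68] [--prevalence 0.41]
#     [--seed 1] [--rois all] [--out results]

suppressMessages({ library(optparse); library(sabradiomics) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 68L),
  make_option("--prevalence", type = "double", default = 0.41),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--rois", type = "character", default = "all"),
  make_option("--out", type = "character", default = "results")
)))

kinds <- if (opts$rois == "all") roi_kinds() else strsplit(opts$rois, ",")[[1]]
cohort <- generate_cohort(phantom_params(n_cases = opts$n,
                                         prevalence = opts$prevalence,
                                         seed = opts$seed))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
for (kind in kinds) {
  t0 <- Sys.time()
  ft <- extract_cohort(cohort, kind)
  path <- file.path(opts$out, sprintf("features_%s.csv", kind))
  write_feature_table(ft, path)
  cat(sprintf("%-14s %d x %d features -> %s (%.0f s)\n", kind,
              nrow(ft$features), ncol(ft$features), path,
              as.numeric(Sys.time() - t0, units = "secs")))
}
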