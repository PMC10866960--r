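#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic post-SABR cohort.
#
# Generates n patients whose SABR-treated lesion has just triggered
# RECIST 1.1 progressive disease, with recurrence prevalence, lesion
# size (mean RECIST length ~55 mm) and voxel geometry matching the
# study conditions, and writes the serial RECIST annotation table.
#
#   Rscript analysis/01_simulate_cohort.R [--n 68] [--prevalence 0.41]
#     [--seed 1] [--out results/cohort] [--write-volumes]

suppressMessages({ library(optparse); library(sabradiomics) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 68L),
  make_option("--prevalence", type = "double", default = 0.41),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/cohort"),
  make_option("--write-volumes", action = "store_true", default = FALSE,
              dest = "write_volumes")
)))

params <- phantom_params(n_cases = opts$n, prevalence = opts$prevalence,
                         seed = opts$seed)
cohort <- generate_cohort(params)
csv <- write_cohort(cohort, opts$out, write_volumes = opts$write_volumes)

lens <- vapply(cohort, function(cs) recist_length(cs$recist_pd), numeric(1))
labs <- vapply(cohort, `[[`, character(1), "label")
pd <- vapply(cohort, `[[`, integer(1), "pd_scan_index")
cat(sprintf("simulated %d cases (%d recurrence / %d RILI)\n",
            length(cohort), sum(labs == "recurrence"), sum(labs == "rili")))
cat(sprintf("RECIST length at progression: mean %.1f mm (range %.1f-%.1f)\n",
            mean(lens), min(lens), max(lens)))
cat(sprintf("progressive disease triggered at scan: %s\n",
            paste(names(table(pd)), table(pd), sep = "x", collapse = ", ")))
cat(sprintf("annotation table: %s\n", csv))
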