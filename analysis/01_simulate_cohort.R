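#!/usr/bin/env Rscript
# Simulate the synthetic multiregion cohort (10 patients, 7 Mut / 3 WT,
# 4-5 primary regions + 2-4 metastases each) and write it, with ground
# truth, under results/cohort/.
suppressPackageStartupMessages(library(mrsevo))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

out <- file.path("results", "cohort")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_multiregion_cohort(seed = seed)
write_cohort(cohort, out)
writeLines(as.character(seed), file.path(out, "seed.txt"))

cat("cohort: ", length(unique(cohort$sheet$patient_id)), " patients, ",
    nrow(cohort$sheet), " samples, seed ", seed, "\n", sep = "")
cat("written to ", out, "\n", sep = "")
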