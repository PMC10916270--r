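#!/usr/bin/env Rscript
# Per-patient sample phylogenies (NJ with 100-replicate bootstrap) on
# the binary mutation matrix with a germline outgroup, plus the
# metastatic-origin classification per site.
suppressPackageStartupMessages(library(mrsevo))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cohort_dir <- file.path("results", "cohort")
out <- file.path("results", "phylogeny")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- list(
  sheet = read_sample_sheet(file.path(cohort_dir, "sample_sheet.tsv")),
  variants = read_variant_table(file.path(cohort_dir, "variants.maf")),
  segments = read_segments(file.path(cohort_dir, "segments.seg")))
processed <- process_cohort(cohort)

origins <- list()
for (pid in names(processed$by_patient)) {
  ph <- patient_phylogeny(processed, pid, builder = "nj",
                          bootstrap = 100, seed = seed)
  write_tree(ph$tree, file.path(out, paste0(pid, "_nj.nwk")))
  origins[[pid]] <- data.frame(patient_id = pid,
                               site = names(ph$met_origin),
                               origin = unname(ph$met_origin))
}
orig <- do.call(rbind, origins)
write.table(orig, file.path(out, "met_origin.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("patients:", length(unique(orig$patient_id)), "\n")
print(table(orig$origin))
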