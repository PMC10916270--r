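#!/usr/bin/env Rscript
# Apply purity exclusion, the variant filter cascade and CCF/clonality
# annotation to the cohort under results/cohort/, writing per-sample
# annotated variant tables and a filter report.
suppressPackageStartupMessages(library(mrsevo))

cohort_dir <- file.path("results", "cohort")
out <- file.path("results", "annotated")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- list(
  sheet = read_sample_sheet(file.path(cohort_dir, "sample_sheet.tsv")),
  variants = read_variant_table(file.path(cohort_dir, "variants.maf")),
  segments = read_segments(file.path(cohort_dir, "segments.seg")))

processed <- process_cohort(cohort)

for (sid in names(processed$annotated)) {
  write.table(processed$annotated[[sid]],
              file.path(out, paste0(sid, "_annotated.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

reasons <- table(unlist(lapply(processed$rejected, `[[`, "reason")))
report <- data.frame(reason = names(reasons), n = as.integer(reasons))
write.table(report, file.path(out, "filter_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(processed$sheet, file.path(out, "retained_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_kept <- sum(vapply(processed$annotated, nrow, integer(1)))
cat("retained samples:", nrow(processed$sheet),
    " retained variants:", n_kept, "\n")
print(report)
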