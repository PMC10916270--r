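#!/usr/bin/env Rscript
# Cohort-level Mut vs WT comparisons: per-metric per-site group report
# (Mann-Whitney / Fisher with BH) and Kaplan-Meier survival with the
# log-rank test on the synthetic follow-up columns.
suppressPackageStartupMessages(library(mrsevo))

cohort_dir <- file.path("results", "cohort")
out <- file.path("results", "cohort_stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- list(
  sheet = read_sample_sheet(file.path(cohort_dir, "sample_sheet.tsv")),
  variants = read_variant_table(file.path(cohort_dir, "variants.maf")),
  segments = read_segments(file.path(cohort_dir, "segments.seg")))
processed <- process_cohort(cohort)

metrics <- sample_metrics(processed)
rep <- group_report(metrics, c("math", "tmb", "tnb", "msi"))
write.table(rep, file.path(out, "group_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(rep[!rep$skipped, c("metric", "stratum", "mean_mut", "mean_wt",
                          "p", "fdr")])

# patient-level survival: one row per patient
pat <- metrics[!duplicated(metrics$patient_id), ]
if (all(c("os_months", "os_event") %in% names(pat))) {
  km <- km_logrank(pat$os_months, pat$os_event, pat$group)
  write.table(km$curves, file.path(out, "km_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("median OS:", paste(names(km$median), round(km$median, 2),
                          collapse = "  "),
      " log-rank p =", round(km$p, 4), "\n")
} else {
  cat("no survival columns in the sample sheet; skipping KM\n")
}
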