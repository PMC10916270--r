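#!/usr/bin/env Rscript
# Genomic scar scores (LOH / TAI / LST, HRD sum), ploidy and WGD call
# per sample, on the cohort's allele-specific segments.
suppressPackageStartupMessages(library(mrsevo))

cohort_dir <- file.path("results", "cohort")
out <- file.path("results", "cnv")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

segments <- read_segments(file.path(cohort_dir, "segments.seg"))
genome <- genome_arms("toy")  # the synthetic cohort's genome annotation

rows <- lapply(names(segments), function(sid) {
  s <- scar_scores(segments[[sid]], genome)
  data.frame(sample_id = sid, loh = s$loh, tai = s$tai, lst = s$lst,
             hrd_sum = s$hrd_sum, ploidy = s$ploidy, wgd = s$wgd)
})
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "scar_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("samples:", nrow(tab), " WGD calls:", sum(tab$wgd),
    " mean HRD sum:", round(mean(tab$hrd_sum), 2), "\n")
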