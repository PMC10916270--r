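#!/usr/bin/env Rscript
# 96-channel mutation catalogs per sample, de novo NMF signature
# extraction with cophenetic rank selection, and cosine matching against
# the bundled synthetic reference signatures.
suppressPackageStartupMessages(library(mrsevo))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cohort_dir <- file.path("results", "cohort")
out <- file.path("results", "signatures")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

variants <- read_variant_table(file.path(cohort_dir, "variants.maf"))
catalogs <- vapply(variants, function(v) as.numeric(catalog_96(v)),
                   numeric(96))
rownames(catalogs) <- channel_names_96()
keep <- colSums(catalogs) > 0
catalogs <- catalogs[, keep, drop = FALSE]
write.table(data.frame(channel = rownames(catalogs), catalogs,
                       check.names = FALSE),
            file.path(out, "catalogs_96.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

res <- nmf_denovo(catalogs, k_range = 2:4, n_restarts = 10, seed = seed)
cat("selected rank k =", res$k, "\n")

ref <- synthetic_reference_signatures()
matches <- do.call(rbind, lapply(seq_len(res$k), function(j) {
  m <- match_cosine(res$signatures[, j], ref)
  data.frame(denovo = paste0("sig", j), best_match = m$best_id,
             cosine = round(m$similarity, 4))
}))
print(matches)

write.table(data.frame(channel = rownames(res$signatures), res$signatures),
            file.path(out, "denovo_signatures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = colnames(res$exposures),
                       t(res$exposures)),
            file.path(out, "exposures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(matches, file.path(out, "reference_matches.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
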