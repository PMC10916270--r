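# Small fixture builders shared across the test files.

# A minimal retained-variant data frame with sensible defaults; any
# column can be overridden via `...` (recycled to `n`).
make_variants <- function(n = 1, ...) {
  v <- data.frame(
    chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
    ref = rep("C", n), alt = rep("T", n),
    variant_type = rep("SNV", n), variant_class = rep("missense", n),
    gene = paste0("G", seq_len(n), recycle0 = TRUE),
    ref_count = rep(160L, n),
    alt_count = rep(40L, n), context = rep("ACA", n),
    population_af = rep(0, n), strand_bias = rep(FALSE, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- rep_len(over[[nm]], n)
  v
}

# Diploid single-segment table covering the toy genome.
make_segments <- function(major = 1L, minor = 1L) {
  g <- genome_arms("toy")
  data.frame(chrom = g$chrom, start = 1L, end = as.integer(g$length),
             major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
}

# A random additive (ultrametric-free) tree distance fixture: generate
# a random topology with positive branch lengths and return its
# patristic distance matrix plus the tree.
random_additive_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, rooted = FALSE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.5, 2)
  list(tree = tree, dist = ape::cophenetic.phylo(tree))
}

# Write a list of per-sample variant data frames to a temporary
# minimal-MAF file and return the path.
write_temp_maf <- function(variants) {
  path <- tempfile(fileext = ".maf")
  write_variant_table(variants, path)
  path
}

# Perfect binary matrix on a known rooted tree over sample tips: every
# edge receives `k` unique mutation columns; each sample carries the
# columns on its root path; germline carries none. Hamming distances
# are exactly additive on the tree with germline attached at the root.
matrix_on_tree <- function(tree, k_range = 1:4) {
  n_tip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  k <- sample(k_range, nrow(tree$edge), replace = TRUE)
  edge_cols <- split(seq_len(sum(k)), rep(seq_len(nrow(tree$edge)), k))
  edge_of <- stats::setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  root <- n_tip + 1
  mat <- matrix(0L, n_tip + 1, sum(k))
  for (i in seq_len(n_tip)) {
    v <- i
    while (v != root) {
      mat[i, edge_cols[[edge_of[[as.character(v)]]]]] <- 1L
      v <- parent[v]
    }
  }
  rownames(mat) <- c(tree$tip.label, "germline")
  colnames(mat) <- paste0("chr1:", seq_len(ncol(mat)), ":C:T")
  mat
}

# The true unrooted topology of matrix_on_tree: `tree` with the
# germline tip attached at its root.
tree_with_germline <- function(tree) {
  nwk <- sub(";$", "", ape::write.tree(ape::compute.brlen(tree, 1)))
  ape::read.tree(text = paste0("(", nwk, ",germline:1);"))
}

# Small cBioPortal-format clinical + mutation fixture pair; returns the
# two file paths.
write_cbio_fixture <- function() {
  dir <- tempfile(); dir.create(dir)
  clin <- file.path(dir, "clinical.txt")
  writeLines(c(
    "#Patient Identifier\tTMB\tMSI\tOS months\tOS status\tCNA",
    "#comment line 2",
    paste("PATIENT_ID", "TMB_NONSYNONYMOUS", "MSI_SCORE", "OS_MONTHS",
          "OS_STATUS", "CNA_COUNT", sep = "\t"),
    "P-0000001\t7.5\t0.2\t40.0\t1:DECEASED\t3",
    "P-0000002\t2.0\t0.1\t55.0\t0:LIVING\t0",
    "P-0000003\t1.0\t0.0\t10.0\t0:LIVING\t0"), clin)
  mut <- file.path(dir, "mutations.txt")
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode",
    "MEN1\tP-0000001-T01-IM6",
    "TP53\tP-0000001-T01-IM6",
    "KRAS\tP-0000002-T02-IM6"), mut)
  list(clinical = clin, mutations = mut)
}
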