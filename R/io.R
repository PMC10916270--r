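# Readers and writers for the tabular formats the pipeline consumes:
# a minimal MAF dialect, SEG-like allele-specific segments, a sample sheet,
# and Newick trees. All text formats are UTF-8, tab-separated, "." = missing.

VARIANT_REQUIRED_COLS <- c("sample_id", "chrom", "pos", "ref", "alt",
                           "variant_type", "variant_class", "gene",
                           "ref_count", "alt_count")
VARIANT_OPTIONAL_COLS <- c("context", "population_af", "strand_bias")

VARIANT_TYPES   <- c("SNV", "INS", "DEL")
VARIANT_CLASSES <- c("missense", "nonsense", "nonstop", "frameshift_indel",
                     "inframe_indel", "splice_site", "synonymous", "other")
SAMPLE_SITES    <- c("primary", "lymph_node", "liver")

#' Variant classes that count toward tumor mutation burden
#'
#' Missense, nonsense, nonstop, frameshift indel, in-frame indel and
#' splice-site mutations; synonymous and other classes are excluded.
#' @return Character vector of class labels.
#' @export
tmb_classes <- function() {
  c("missense", "nonsense", "nonstop", "frameshift_indel",
    "inframe_indel", "splice_site")
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = ".", colClasses = "character",
                    check.names = FALSE, comment.char = "")
}

check_required_cols <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

# Strict integer conversion with row-level error reporting. `line_offset`
# converts a data row index into a file line number (1 = header).
as_count <- function(x, col, line_offset = 1L) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & (is.na(out) | out != suppressWarnings(as.numeric(x))))
  if (length(bad) > 0) {
    stop("non-integer value '", x[bad[1]], "' in column '", col,
         "' at line ", bad[1] + line_offset)
  }
  out
}

as_num <- function(x, col, line_offset = 1L) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("non-numeric value '", x[bad[1]], "' in column '", col,
         "' at line ", bad[1] + line_offset)
  }
  out
}

#' Read a somatic variant table
#'
#' Reads either the package's minimal MAF dialect (tab-separated, one row
#' per variant per sample) or a VCF (read-only; the AD FORMAT field supplies
#' ref/alt counts and multi-allelic records are split).
#'
#' @param path Path to the file.
#' @param dialect `"maf_min"` (default) or `"vcf"`.
#' @return A named list, one data frame of variant records per sample, in
#'   file row order. Each data frame carries the columns
#'   `chrom, pos, ref, alt, variant_type, variant_class, gene, ref_count,
#'   alt_count, context, population_af, strand_bias`.
#' @export
read_variant_table <- function(path, dialect = c("maf_min", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_variant_vcf(path))
  df <- read_tsv_raw(path)
  check_required_cols(df, VARIANT_REQUIRED_COLS, path)
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  out <- data.frame(
    sample_id     = df$sample_id,
    chrom         = df$chrom,
    pos           = as_count(df$pos, "pos"),
    ref           = df$ref,
    alt           = df$alt,
    variant_type  = df$variant_type,
    variant_class = df$variant_class,
    gene          = df$gene,
    ref_count     = as_count(df$ref_count, "ref_count"),
    alt_count     = as_count(df$alt_count, "alt_count"),
    stringsAsFactors = FALSE
  )
  out$context <- if ("context" %in% names(df)) df$context else NA_character_
  out$population_af <- if ("population_af" %in% names(df))
    as_num(df$population_af, "population_af") else NA_real_
  out$strand_bias <- if ("strand_bias" %in% names(df))
    tolower(df$strand_bias) %in% c("true", "1", "t", "yes") else FALSE
  validate_variants(out)
  split_keep_order(out[, -1], out$sample_id)
}

validate_variants <- function(v) {
  if (any(v$pos < 1, na.rm = TRUE)) stop("pos must be >= 1")
  if (any(v$ref_count < 0 | v$alt_count < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  bad_type <- setdiff(unique(v$variant_type), VARIANT_TYPES)
  if (length(bad_type) > 0) stop("unknown variant_type: ", bad_type[1])
  ctx <- v$context[!is.na(v$context)]
  if (length(ctx) > 0 && any(nchar(ctx) != 3 | !substr(ctx, 2, 2) %in% c("C", "T")))
    stop("trinucleotide context must be length 3 with pyrimidine middle base")
  invisible(v)
}

# split() reorders by factor level; keep first-appearance order of samples.
split_keep_order <- function(df, key) {
  lv <- unique(key)
  out <- split(df, factor(key, levels = lv))
  lapply(out, function(x) { rownames(x) <- NULL; x })
}

#' Write a somatic variant table in the minimal MAF dialect
#'
#' @param variants_by_sample Named list of variant data frames, as returned
#'   by [read_variant_table()].
#' @param path Output path.
#' @export
write_variant_table <- function(variants_by_sample, path) {
  rows <- lapply(names(variants_by_sample), function(s) {
    v <- variants_by_sample[[s]]
    if (nrow(v) == 0) return(NULL)
    cbind(sample_id = s, v[, c(VARIANT_REQUIRED_COLS[-1], VARIANT_OPTIONAL_COLS)])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(matrix(ncol = length(c(VARIANT_REQUIRED_COLS, VARIANT_OPTIONAL_COLS)),
                            nrow = 0))
    names(df) <- c(VARIANT_REQUIRED_COLS, VARIANT_OPTIONAL_COLS)
  }
  df$strand_bias <- ifelse(is.na(df$strand_bias), ".",
                           ifelse(df$strand_bias, "true", "false"))
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.numeric(col)) col <- format(col, trim = TRUE, scientific = FALSE, digits = 12)
    col[is.na(df[[j]])] <- "."
    df[[j]] <- col
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF has no AD FORMAT field")
  samples <- colnames(ad)
  out <- list()
  for (s in samples) {
    recs <- list()
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      counts <- suppressWarnings(as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      for (k in seq_along(alts)) {
        alt <- alts[k]
        ref <- fix$REF[i]
        type <- if (nchar(ref) == nchar(alt)) "SNV"
                else if (nchar(alt) > nchar(ref)) "INS" else "DEL"
        recs[[length(recs) + 1]] <- data.frame(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = ref,
          alt = alt, variant_type = type, variant_class = "other",
          gene = NA_character_, ref_count = counts[1],
          alt_count = if (length(counts) > k) counts[k + 1] else NA_integer_,
          context = NA_character_, population_af = NA_real_,
          strand_bias = FALSE, stringsAsFactors = FALSE)
      }
    }
    out[[s]] <- do.call(rbind, recs)
  }
  out
}

#' Read allele-specific copy-number segments
#'
#' SEG-like tab-separated file with columns
#' `sample, chrom, start, end, major_cn, minor_cn` (1-based inclusive
#' coordinates). Segments are grouped by sample and sorted by
#' (chrom, start); overlapping segments within a chromosome are rejected.
#'
#' @param path Path to the segment file.
#' @return Named list of per-sample segment data frames.
#' @export
read_segments <- function(path) {
  df <- read_tsv_raw(path)
  check_required_cols(df, c("sample", "chrom", "start", "end", "major_cn", "minor_cn"), path)
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  seg <- data.frame(
    sample   = df$sample,
    chrom    = df$chrom,
    start    = as_count(df$start, "start"),
    end      = as_count(df$end, "end"),
    major_cn = as_count(df$major_cn, "major_cn"),
    minor_cn = as_count(df$minor_cn, "minor_cn"),
    stringsAsFactors = FALSE
  )
  lapply(split_keep_order(seg[, -1], seg$sample), validate_segments)
}

validate_segments <- function(seg) {
  if (any(seg$major_cn < seg$minor_cn))
    stop("format error: major_cn < minor_cn")
  if (any(seg$minor_cn < 0)) stop("copy numbers must be >= 0")
  if (any(seg$end < seg$start)) stop("segment end < start")
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  by_chr <- split(seg, seg$chrom)
  for (ch in by_chr) {
    if (nrow(ch) > 1 && any(ch$start[-1] <= ch$end[-nrow(ch)]))
      stop("validation error: overlapping segments on ", ch$chrom[1])
  }
  rownames(seg) <- NULL
  seg
}

#' Read the cohort sample sheet
#'
#' Tab-separated file with columns `sample_id, patient_id, site,
#' region_index, purity, group` (optionally `ploidy`). Sites must be one of
#' primary / lymph_node / liver; all samples of a patient must share one
#' Mut/WT group label.
#'
#' @param path Path to the sheet.
#' @return A data frame of samples (the cohort skeleton).
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_raw(path)
  check_required_cols(df, c("sample_id", "patient_id", "site", "region_index",
                            "purity", "group"), path)
  out <- data.frame(
    sample_id    = df$sample_id,
    patient_id   = df$patient_id,
    site         = df$site,
    region_index = as_count(df$region_index, "region_index"),
    purity       = as_num(df$purity, "purity"),
    group        = df$group,
    stringsAsFactors = FALSE
  )
  if ("ploidy" %in% names(df)) out$ploidy <- as_num(df$ploidy, "ploidy")
  validate_sample_sheet(out)
}

validate_sample_sheet <- function(sheet) {
  if (nrow(sheet) == 0) return(sheet)
  bad_site <- setdiff(unique(sheet$site), SAMPLE_SITES)
  if (length(bad_site) > 0)
    stop("validation error: unknown site '", bad_site[1], "'")
  if (any(duplicated(sheet$sample_id)))
    stop("duplicate sample_id in sample sheet")
  if (any(!is.na(sheet$purity) & (sheet$purity <= 0 | sheet$purity > 1)))
    stop("purity must be in (0, 1]")
  gl <- tapply(sheet$group, sheet$patient_id, function(g) length(unique(g)))
  if (any(gl > 1))
    stop("inconsistent group labels within patient ",
         names(gl)[which(gl > 1)[1]])
  sheet
}

#' Write a phylogenetic tree as Newick text
#'
#' Bootstrap supports stored in `tree$node.label` are written as internal
#' node labels.
#'
#' @param tree An [ape::phylo] object with labeled leaves.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("tree has unlabeled leaves")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) ape::read.tree(path)
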