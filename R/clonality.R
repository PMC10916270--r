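# Cancer cell fraction estimation and intratumor-heterogeneity statistics:
# VAF -> multiplicity -> CCF with a Clopper-Pearson interval, the
# clonal/subclonal call, MATH score, TMB, and public/shared/private
# sharing classes with the spatial-ITH fraction.

#' Estimate cancer cell fractions for a sample's variants
#'
#' Applies the standard purity/copy-number correction. With tumor purity
#' `rho`, locus total copy number `CN_t = major + minor` and mutation
#' multiplicity `m`, the expected VAF of a mutation at cancer cell
#' fraction CCF is `rho * CCF * m / (rho * CN_t + 2 * (1 - rho))`.
#' Inverting: multiplicity is estimated as
#' `m = clamp(round(vaf / rho * (rho * CN_t + 2 (1 - rho))), 1, major)` and
#' `CCF = vaf * (rho * CN_t + 2 (1 - rho)) / (rho * m)`. A 95%
#' Clopper-Pearson interval on the alt-read fraction is propagated through
#' the same linear map. Loci with no covering segment are treated as
#' diploid heterozygous (1+1), with a message.
#'
#' @param variants Data frame of variant records for one sample.
#' @param purity Tumor purity in (0, 1].
#' @param segments Data frame of allele-specific segments
#'   (`chrom,start,end,major_cn,minor_cn`), or NULL for an all-diploid
#'   assumption.
#' @param conf_level Confidence level of the CCF interval.
#' @return The input data frame with columns `vaf, cn_total, multiplicity,
#'   ccf, ccf_low, ccf_high` appended. `ccf` is the raw estimate (can
#'   exceed 1 through sampling noise); clip for reporting if needed.
#' @export
compute_ccf <- function(variants, purity, segments = NULL, conf_level = 0.95) {
  stopifnot(purity > 0, purity <= 1)
  v <- variants
  n <- nrow(v)
  cn <- locus_copy_number(v, segments)
  if (any(cn$cn_total == 0))
    stop("total copy number 0 at a mutated locus (inconsistent input)")
  depth <- v$ref_count + v$alt_count
  vaf <- ifelse(depth > 0, v$alt_count / depth, 0)
  denom <- purity * cn$cn_total + 2 * (1 - purity)
  mult <- pmin(pmax(round(vaf / purity * denom), 1), pmax(cn$major_cn, 1))
  ccf <- vaf * denom / (purity * mult)
  ci <- t(vapply(seq_len(n), function(i) {
    if (depth[i] == 0) return(c(0, 1))
    stats::binom.test(v$alt_count[i], depth[i],
                      conf.level = conf_level)$conf.int
  }, numeric(2)))
  v$vaf <- vaf
  v$cn_total <- cn$cn_total
  v$multiplicity <- mult
  v$ccf <- ccf
  v$ccf_low <- ci[, 1] * denom / (purity * mult)
  v$ccf_high <- ci[, 2] * denom / (purity * mult)
  v
}

# Allele-specific copy number at each variant locus; 1+1 where no segment
# covers the position.
locus_copy_number <- function(variants, segments) {
  n <- nrow(variants)
  major <- rep(1L, n)
  minor <- rep(1L, n)
  if (!is.null(segments) && nrow(segments) > 0 && n > 0) {
    hit <- rep(FALSE, n)
    for (i in seq_len(n)) {
      j <- which(segments$chrom == variants$chrom[i] &
                 segments$start <= variants$pos[i] &
                 segments$end >= variants$pos[i])
      if (length(j) > 0) {
        major[i] <- segments$major_cn[j[1]]
        minor[i] <- segments$minor_cn[j[1]]
        hit[i] <- TRUE
      }
    }
    if (any(!hit)) message(sum(!hit), " variant(s) outside segments; assuming 1+1")
  }
  list(major_cn = major, minor_cn = minor, cn_total = major + minor)
}

#' Classify variants as clonal or subclonal
#'
#' A variant is clonal when its point CCF is at least `ccf_cutoff` or its
#' confidence interval reaches 1 (the mutation is consistent with presence
#' in all tumor cells); otherwise subclonal.
#'
#' @param ccf_annotated Data frame from [compute_ccf()].
#' @param ccf_cutoff Point-estimate cutoff (default 0.85).
#' @return The data frame with a `clonality` column (`"clonal"` /
#'   `"subclonal"`).
#' @export
classify_clonality <- function(ccf_annotated, ccf_cutoff = 0.85) {
  v <- ccf_annotated
  v$clonality <- ifelse(v$ccf >= ccf_cutoff | v$ccf_high >= 1,
                        "clonal", "subclonal")
  v
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' `100 * MAD(vaf) / median(vaf)`, with the median absolute deviation
#' scaled by the 1.4826 normal-consistency constant.
#'
#' @param vafs Numeric vector of variant allele frequencies (>= 3 values).
#' @return The MATH score (0 when all VAFs are equal).
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 3) stop("MATH requires at least 3 VAFs")
  med <- stats::median(vafs)
  if (med == 0) stop("median VAF is 0; MATH undefined")
  100 * stats::mad(vafs, constant = 1.4826) / med
}

#' Tumor mutation burden
#'
#' Counts filtered mutations in the missense, nonsense, nonstop,
#' frameshift-indel, in-frame-indel and splice-site classes, per megabase
#' of captured exome.
#'
#' @param variants Data frame of retained variant records.
#' @param panel_mb Size of the capture panel in Mb (default 30).
#' @return Mutations per Mb.
#' @export
tmb <- function(variants, panel_mb = 30) {
  stopifnot(panel_mb > 0)
  sum(variants$variant_class %in% tmb_classes()) / panel_mb
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Public / shared / private sharing classes for one patient
#'
#' Each unique variant (keyed by chrom, pos, ref, alt) is public when
#' present in all of the patient's samples, private when present in exactly
#' one, and shared otherwise. Spatial intratumor heterogeneity is the
#' fraction of unique variants that are not public.
#'
#' @param variants_by_sample Named list of retained variant data frames,
#'   one per sample of a single patient (>= 2 samples).
#' @return A list with `classes` (data frame: key, gene, n_samples, class),
#'   `proportions` (named numeric over public/shared/private) and
#'   `spatial_ith`.
#' @export
classify_sharing <- function(variants_by_sample) {
  if (length(variants_by_sample) < 2)
    stop("sharing classes need >= 2 samples")
  n_samp <- length(variants_by_sample)
  keys <- lapply(variants_by_sample, function(v) unique(variant_key(v)))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  counts <- rowSums(matrix(vapply(keys, function(k) all_keys %in% k,
                                  logical(length(all_keys))),
                           nrow = length(all_keys)))
  cls <- ifelse(counts == n_samp, "public",
                ifelse(counts == 1, "private", "shared"))
  gene_map <- do.call(rbind, lapply(variants_by_sample, function(v)
    data.frame(key = variant_key(v), gene = v$gene, stringsAsFactors = FALSE)))
  gene <- gene_map$gene[match(all_keys, gene_map$key)]
  classes <- data.frame(key = all_keys, gene = gene, n_samples = counts,
                        class = cls, stringsAsFactors = FALSE)
  prop <- prop.table(table(factor(cls, levels = c("public", "shared", "private"))))
  list(classes = classes,
       proportions = c(prop),
       spatial_ith = 1 - sum(cls == "public") / length(all_keys))
}

#' Mean variant prevalence of a gene set
#'
#' For each unique variant in the listed genes, the fraction of the
#' patient's samples carrying it; averaged over variants and patients.
#' An interpretation of per-variant carrier prevalence (no formula is
#' standard); reported as a plain mean over variants.
#'
#' @param cohort_variants Named list (patient) of named lists (sample) of
#'   retained variant data frames.
#' @param genes Character vector of gene symbols; NULL for all genes.
#' @return Mean prevalence in [0, 1], or NA when no qualifying variant.
#' @export
variant_prevalence <- function(cohort_variants, genes = NULL) {
  prevs <- unlist(lapply(cohort_variants, function(samples) {
    if (length(samples) == 0) return(NULL)
    keys <- lapply(samples, function(v) {
      if (!is.null(genes)) v <- v[v$gene %in% genes, , drop = FALSE]
      unique(variant_key(v))
    })
    all_keys <- unique(unlist(keys, use.names = FALSE))
    if (length(all_keys) == 0) return(NULL)
    counts <- rowSums(matrix(vapply(keys, function(k) all_keys %in% k,
                                    logical(length(all_keys))),
                             nrow = length(all_keys)))
    counts / length(samples)
  }), use.names = FALSE)
  if (length(prevs) == 0) return(NA_real_)
  mean(prevs)
}
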