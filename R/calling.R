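# Binomial-test variant detection and the filter cascade applied after
# calling: depth, alt-read support, allele frequency, indel length,
# population prevalence, strand bias, and low-purity sample exclusion.

#' Default filter thresholds
#'
#' The detection thresholds of the pipeline: depth >= 30, >= 4 supporting
#' reads, VAF strictly > 3%, indels <= 40 bp, population allele frequency
#' < 1%, a binomial detection test at `alpha` against a sequencing error
#' rate, and sample purity >= 30%. The binomial model's error rate and
#' alpha are assumptions of this implementation and are configurable.
#'
#' @param min_depth,min_alt_reads,min_vaf,max_indel_bp,max_population_af
#'   Variant-level thresholds.
#' @param alpha,error_rate Binomial detection test parameters.
#' @param min_purity Sample-level purity cutoff.
#' @return A list of thresholds.
#' @export
filter_thresholds <- function(min_depth = 30, min_alt_reads = 4,
                              min_vaf = 0.03, max_indel_bp = 40,
                              max_population_af = 0.01, alpha = 0.05,
                              error_rate = 0.005, min_purity = 0.30) {
  stopifnot(min_depth > 0, min_alt_reads > 0, min_vaf > 0, min_vaf < 1,
            max_indel_bp > 0, max_population_af > 0, alpha > 0,
            error_rate > 0, error_rate < 1, min_purity > 0)
  list(min_depth = min_depth, min_alt_reads = min_alt_reads,
       min_vaf = min_vaf, max_indel_bp = max_indel_bp,
       max_population_af = max_population_af, alpha = alpha,
       error_rate = error_rate, min_purity = min_purity)
}

#' Binomial variant detection test
#'
#' Upper-tail exact binomial test of the observed alt-read count against a
#' background sequencing error rate: `p = P(X >= alt_count)` for
#' `X ~ Binomial(depth, error_rate)`. A variant is called when `p < alpha`.
#'
#' @param alt_count Alt-supporting read count (vectorized).
#' @param depth Total read depth.
#' @param error_rate Per-read error probability.
#' @param alpha Significance level.
#' @return A list with `is_called` (logical) and `p_value`.
#' @export
binomial_call <- function(alt_count, depth, error_rate = 0.005, alpha = 0.05) {
  if (any(alt_count > depth)) stop("alt_count exceeds depth")
  if (any(alt_count < 0 | depth < 0)) stop("counts must be non-negative")
  stopifnot(error_rate > 0, error_rate < 1)
  p <- stats::pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
  list(is_called = p < alpha, p_value = p)
}

FILTER_REASONS <- c("depth", "alt", "vaf", "indel_len", "pop_af",
                    "binomial", "strand_bias")

indel_length <- function(ref, alt) abs(nchar(alt) - nchar(ref))

#' Apply the somatic variant filter cascade
#'
#' Retains a variant iff depth >= `min_depth`, alt reads >= `min_alt_reads`,
#' VAF strictly > `min_vaf`, indel length <= `max_indel_bp` (SNVs always
#' pass), population allele frequency missing or < `max_population_af`,
#' the binomial detection test calls it, and the strand-bias flag is unset.
#' Rejected variants carry the first failing reason in the fixed order
#' depth, alt, vaf, indel_len, pop_af, binomial, strand_bias.
#'
#' @param variants Data frame of variant records (one sample).
#' @param thresholds A list from [filter_thresholds()].
#' @return A list with `retained` (data frame) and `rejected` (data frame
#'   with an extra `reason` column).
#' @export
apply_variant_filters <- function(variants, thresholds = filter_thresholds()) {
  v <- variants
  if (nrow(v) == 0) {
    return(list(retained = v, rejected = cbind(v, reason = character(0))))
  }
  depth <- v$ref_count + v$alt_count
  vaf <- ifelse(depth > 0, v$alt_count / depth, 0)
  bc <- binomial_call(v$alt_count, depth, thresholds$error_rate, thresholds$alpha)
  sb <- if ("strand_bias" %in% names(v)) v$strand_bias %in% TRUE else rep(FALSE, nrow(v))
  fail <- cbind(
    depth       = depth < thresholds$min_depth,
    alt         = v$alt_count < thresholds$min_alt_reads,
    vaf         = vaf <= thresholds$min_vaf,
    indel_len   = v$variant_type != "SNV" &
                    indel_length(v$ref, v$alt) > thresholds$max_indel_bp,
    pop_af      = !is.na(v$population_af) &
                    v$population_af >= thresholds$max_population_af,
    binomial    = !bc$is_called,
    strand_bias = sb
  )
  first_fail <- apply(fail, 1, function(r) {
    i <- which(r)
    if (length(i) == 0) NA_character_ else FILTER_REASONS[i[1]]
  })
  keep <- is.na(first_fail)
  rejected <- v[!keep, , drop = FALSE]
  rejected$reason <- first_fail[!keep]
  retained <- v[keep, , drop = FALSE]
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Exclude low-purity samples
#'
#' Samples with tumor purity below 30% (strictly less) are removed from the
#' cohort before genome characterization.
#'
#' @param sheet Sample sheet data frame with a `purity` column.
#' @param min_purity Purity cutoff; samples with `purity >= min_purity`
#'   are retained.
#' @return The retained rows of `sheet`; excluded sample ids are reported
#'   via `message()`.
#' @export
exclude_low_purity <- function(sheet, min_purity = 0.30) {
  if (any(is.na(sheet$purity))) stop("missing purity for sample(s): ",
    paste(sheet$sample_id[is.na(sheet$purity)], collapse = ", "))
  drop <- sheet$purity < min_purity
  if (any(drop)) {
    message("excluding low-purity sample(s): ",
            paste(sheet$sample_id[drop], collapse = ", "))
  }
  out <- sheet[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
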