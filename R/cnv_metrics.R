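# Genomic scar scores from allele-specific copy-number segments:
# HRD-LOH (large-scale loss of heterozygosity), TAI (telomeric allelic
# imbalance), LST (large-scale state transitions), their HRD sum, the
# length-weighted ploidy, and a whole-genome duplication call.

#' Autosome arm annotation
#'
#' Chromosome lengths and centromere boundaries for the 22 human autosomes
#' (hg19 coordinates), or a small toy genome used in examples and tests
#' (3 chromosomes of 100/80/60 Mb with centromeres at mid-chromosome).
#'
#' @param genome `"hg19"` or `"toy"`.
#' @return Data frame with columns `chrom, length, cen_start, cen_end`.
#' @export
genome_arms <- function(genome = c("hg19", "toy")) {
  genome <- match.arg(genome)
  if (genome == "toy") {
    return(data.frame(
      chrom = c("chr1", "chr2", "chr3"),
      length = c(100e6, 80e6, 60e6),
      cen_start = c(48e6, 38e6, 28e6),
      cen_end = c(52e6, 42e6, 32e6)))
  }
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566),
    cen_start = c(121535434, 92326171, 90504854, 49660117, 46405641,
                  58830166, 58054331, 43838887, 47367679, 39254935,
                  51644205, 34856694, 16000000, 16000000, 17000000,
                  35335801, 22263006, 15460898, 24681782, 26369569,
                  11288129, 13000000),
    cen_end = c(124535434, 95326171, 93504854, 52660117, 49405641,
                61830166, 61054331, 46838887, 50367679, 42254935,
                54644205, 37856694, 19000000, 19000000, 20000000,
                38335801, 25263006, 18460898, 27681782, 29369569,
                14288129, 16000000))
}

seg_len <- function(seg) seg$end - seg$start + 1

# Merge adjacent segments with identical copy numbers when the gap between
# them is below `max_gap` (smoothing).
merge_same_cn <- function(seg, max_gap = Inf) {
  if (nrow(seg) <= 1) return(seg)
  seg <- seg[order(seg$start), , drop = FALSE]
  out <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    last <- nrow(out)
    gap <- seg$start[i] - out$end[last] - 1
    if (seg$major_cn[i] == out$major_cn[last] &&
        seg$minor_cn[i] == out$minor_cn[last] && gap < max_gap) {
      out$end[last] <- seg$end[i]
    } else {
      out <- rbind(out, seg[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Genomic scar scores for one sample
#'
#' * HRD-LOH: segments with minor copy number 0, longer than 15 Mb but
#'   shorter than the whole chromosome.
#' * TAI: allelic-imbalance segments (major != minor) that reach a
#'   telomere but do not cross the centromere.
#' * LST: per chromosome arm, after removing segments shorter than 3 Mb
#'   and smoothing, breakpoints between adjacent segments that are each at
#'   least 10 Mb long and separated by less than 3 Mb.
#'
#' The HRD sum is LOH + TAI + LST.
#'
#' @param segments Data frame of allele-specific segments for one sample.
#' @param genome Arm annotation from [genome_arms()].
#' @param loh_min_len,lst_min_len,lst_smooth_len,telomere_tol Rule lengths
#'   in bp (canonical scar-literature values by default).
#' @return A list with integer `loh`, `tai`, `lst`, `hrd_sum`, plus
#'   `ploidy` and `wgd` from [call_wgd()].
#' @export
scar_scores <- function(segments, genome = genome_arms("hg19"),
                        loh_min_len = 15e6, lst_min_len = 10e6,
                        lst_smooth_len = 3e6, telomere_tol = 1e5) {
  seg <- segments[segments$chrom %in% genome$chrom, , drop = FALSE]
  missing_ann <- setdiff(unique(segments$chrom), genome$chrom)
  # Non-autosomal contigs are simply outside the annotation; a covered
  # autosome without arm boundaries is an error.
  if (length(missing_ann) > 0 && any(grepl("^(chr)?([0-9]+)$", missing_ann)))
    stop("missing arm annotation for chromosome ",
         missing_ann[grepl("^(chr)?([0-9]+)$", missing_ann)][1])
  covered <- sum(seg_len(seg))
  if (covered < 0.9 * sum(genome$length))
    warning("segments cover < 90% of annotated autosomes; scar scores may be unreliable")

  loh <- 0L; tai <- 0L; lst <- 0L
  for (ch in unique(seg$chrom)) {
    ann <- genome[genome$chrom == ch, ]
    s <- merge_same_cn(seg[seg$chrom == ch, , drop = FALSE])
    len <- seg_len(s)
    loh <- loh + sum(s$minor_cn == 0 & len > loh_min_len & len < ann$length)
    imb <- s$major_cn != s$minor_cn
    reach_p <- s$start <= telomere_tol + 1
    reach_q <- s$end >= ann$length - telomere_tol
    cross_cen <- s$start <= ann$cen_end & s$end >= ann$cen_start
    tai <- tai + sum(imb & (reach_p | reach_q) & !cross_cen)
    # LST per arm: clip segments at the centromere midpoint
    cen_mid <- (ann$cen_start + ann$cen_end) / 2
    for (arm in c("p", "q")) {
      a <- s
      if (arm == "p") {
        a <- a[a$start < cen_mid, , drop = FALSE]
        a$end <- pmin(a$end, floor(cen_mid))
      } else {
        a <- a[a$end > cen_mid, , drop = FALSE]
        a$start <- pmax(a$start, ceiling(cen_mid) + 1)
      }
      lst <- lst + count_lst_arm(a, lst_min_len, lst_smooth_len)
    }
  }
  wgd <- call_wgd(segments, genome)
  list(loh = as.integer(loh), tai = as.integer(tai), lst = as.integer(lst),
       hrd_sum = as.integer(loh + tai + lst),
       ploidy = wgd$ploidy, wgd = wgd$wgd)
}

count_lst_arm <- function(seg, min_len, smooth_len) {
  seg <- seg[seg_len(seg) >= smooth_len, , drop = FALSE]
  if (nrow(seg) < 2) return(0L)
  seg <- merge_same_cn(seg, max_gap = smooth_len)
  if (nrow(seg) < 2) return(0L)
  len <- seg_len(seg)
  n <- 0L
  for (i in 2:nrow(seg)) {
    gap <- seg$start[i] - seg$end[i - 1] - 1
    cn_change <- seg$major_cn[i] != seg$major_cn[i - 1] ||
                 seg$minor_cn[i] != seg$minor_cn[i - 1]
    if (cn_change && gap < smooth_len &&
        len[i] >= min_len && len[i - 1] >= min_len) n <- n + 1L
  }
  n
}

#' Ploidy and whole-genome duplication call
#'
#' Ploidy is the segment-length-weighted mean total copy number. WGD is
#' called when the length-weighted fraction of the covered autosomal
#' genome with major copy number >= 2 strictly exceeds 0.5.
#'
#' @param segments Data frame of allele-specific segments.
#' @param genome Arm annotation; only annotated chromosomes contribute.
#' @return A list with `wgd` (logical) and `ploidy`.
#' @export
call_wgd <- function(segments, genome = genome_arms("hg19")) {
  seg <- segments[segments$chrom %in% genome$chrom, , drop = FALSE]
  len <- seg_len(seg)
  total <- sum(len)
  if (total == 0) stop("zero total segment length")
  ploidy <- sum(len * (seg$major_cn + seg$minor_cn)) / total
  frac_major2 <- sum(len[seg$major_cn >= 2]) / total
  list(wgd = frac_major2 > 0.5, ploidy = ploidy)
}
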