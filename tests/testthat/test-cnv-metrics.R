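# cnv_metrics: HRD-LOH / TAI / LST scar scores, ploidy and the WGD call
# on the toy genome (3 chromosomes: 100/80/60 Mb, centromeres at
# 48-52 / 38-42 / 28-32 Mb).

toy <- genome_arms("toy")

# full diploid coverage of the toy genome
diploid <- function() {
  data.frame(chrom = toy$chrom, start = 1, end = toy$length,
             major_cn = 1L, minor_cn = 1L, stringsAsFactors = FALSE)
}

test_that("diploid genome has zero scars, ploidy 2, no WGD", {
  s <- scar_scores(diploid(), toy)
  expect_equal(s[c("loh", "tai", "lst")], list(loh = 0L, tai = 0L, lst = 0L))
  expect_equal(s$hrd_sum, 0L)
  expect_equal(s$ploidy, 2)
  expect_false(s$wgd)
})

test_that("LOH counts >15Mb non-whole-chromosome minor=0 segments", {
  seg <- diploid()
  # 20 Mb interstitial LOH on chr1 q arm
  seg <- rbind(seg[-1, ],
               data.frame(chrom = "chr1", start = 1, end = 59999999,
                          major_cn = 1L, minor_cn = 1L),
               data.frame(chrom = "chr1", start = 60e6, end = 80e6,
                          major_cn = 1L, minor_cn = 0L),
               data.frame(chrom = "chr1", start = 80000001, end = 100e6,
                          major_cn = 1L, minor_cn = 1L))
  s <- scar_scores(seg, toy)
  expect_equal(s$loh, 1L)

  # whole-chromosome LOH does not count
  seg2 <- diploid()
  seg2$minor_cn[seg2$chrom == "chr3"] <- 0L
  expect_equal(scar_scores(seg2, toy)$loh, 0L)

  # exactly 15 Mb does not count (strictly greater required)
  seg3 <- rbind(diploid()[-1, ],
                data.frame(chrom = "chr1", start = 1, end = 15e6,
                           major_cn = 1L, minor_cn = 0L),
                data.frame(chrom = "chr1", start = 15000001, end = 100e6,
                           major_cn = 1L, minor_cn = 1L))
  expect_equal(scar_scores(seg3, toy)$loh, 0L)
})

test_that("TAI requires telomere contact without centromere crossing", {
  # imbalance reaching chr2 p telomere, ending before the centromere
  seg <- rbind(diploid()[-2, ],
               data.frame(chrom = "chr2", start = 1, end = 20e6,
                          major_cn = 2L, minor_cn = 1L),
               data.frame(chrom = "chr2", start = 20000001, end = 80e6,
                          major_cn = 1L, minor_cn = 1L))
  expect_equal(scar_scores(seg, toy)$tai, 1L)

  # same segment but crossing the centromere (ends inside it) -> no TAI
  seg2 <- rbind(diploid()[-2, ],
                data.frame(chrom = "chr2", start = 1, end = 40e6,
                           major_cn = 2L, minor_cn = 1L),
                data.frame(chrom = "chr2", start = 40000001, end = 80e6,
                           major_cn = 1L, minor_cn = 1L))
  expect_equal(scar_scores(seg2, toy)$tai, 0L)

  # interstitial imbalance (no telomere contact) -> no TAI
  seg3 <- rbind(diploid()[-2, ],
                data.frame(chrom = "chr2", start = 1, end = 10e6,
                           major_cn = 1L, minor_cn = 1L),
                data.frame(chrom = "chr2", start = 10000001, end = 25e6,
                           major_cn = 2L, minor_cn = 1L),
                data.frame(chrom = "chr2", start = 25000001, end = 80e6,
                           major_cn = 1L, minor_cn = 1L))
  expect_equal(scar_scores(seg3, toy)$tai, 0L)
})

test_that("LST counts CN changes between >=10Mb neighbors within an arm", {
  # chr1 q arm (50-100 Mb): two 25 Mb segments with a CN change
  seg <- rbind(diploid()[-1, ],
               data.frame(chrom = "chr1", start = 1, end = 75e6,
                          major_cn = 1L, minor_cn = 1L),
               data.frame(chrom = "chr1", start = 75000001, end = 100e6,
                          major_cn = 2L, minor_cn = 1L))
  s <- scar_scores(seg, toy)
  expect_equal(s$lst, 1L)

  # breakpoint where one side is < 10 Mb -> not an LST
  seg2 <- rbind(diploid()[-1, ],
                data.frame(chrom = "chr1", start = 1, end = 95e6,
                           major_cn = 1L, minor_cn = 1L),
                data.frame(chrom = "chr1", start = 95000001, end = 100e6,
                           major_cn = 2L, minor_cn = 1L))
  expect_equal(scar_scores(seg2, toy)$lst, 0L)

  # a breakpoint AT the centromere is clipped away and never counts
  seg3 <- rbind(diploid()[-1, ],
                data.frame(chrom = "chr1", start = 1, end = 50e6,
                           major_cn = 1L, minor_cn = 1L),
                data.frame(chrom = "chr1", start = 50000001, end = 100e6,
                           major_cn = 2L, minor_cn = 1L))
  expect_equal(scar_scores(seg3, toy)$lst, 0L)
})

test_that("scar scores match a rule oracle on random segmentations", {
  # oracle applies each published rule independently on one chromosome
  set.seed(11)
  for (rep in 1:5) {
    # random segmentation of chr1 into 4-8 pieces with random CN states
    k <- sample(4:8, 1)
    cuts <- sort(sample(seq(2e6, 98e6, by = 1e6), k - 1))
    bounds <- cbind(c(1, cuts + 1), c(cuts, 100e6))
    cn <- cbind(sample(0:3, k, TRUE), sample(0:2, k, TRUE))
    seg <- data.frame(chrom = "chr1", start = bounds[, 1], end = bounds[, 2],
                      major_cn = pmax(cn[, 1], cn[, 2]),
                      minor_cn = pmin(cn[, 1], cn[, 2]))
    seg <- seg[seg$major_cn + seg$minor_cn > 0, ]  # avoid 0+0 everywhere
    full <- rbind(seg, diploid()[-1, ])
    got <- suppressWarnings(scar_scores(full, toy))

    # oracle LOH / TAI on the merged segmentation of chr1
    m <- mrsevo:::merge_same_cn(seg)
    len <- m$end - m$start + 1
    o_loh <- sum(m$minor_cn == 0 & len > 15e6 & len < 100e6)
    imb <- m$major_cn != m$minor_cn
    o_tai <- sum(imb & (m$start <= 1e5 + 1 | m$end >= 100e6 - 1e5) &
                   !(m$start <= 52e6 & m$end >= 48e6))
    expect_equal(got$loh, o_loh)
    expect_equal(got$tai, o_tai)
  }
})

test_that("WGD call and length-weighted ploidy", {
  seg <- diploid()
  seg$major_cn <- 2L  # major 2 everywhere
  w <- call_wgd(seg, toy)
  expect_true(w$wgd)
  expect_equal(w$ploidy, 3)

  # exactly 50% of the genome at major >= 2 is NOT WGD (strict)
  seg2 <- diploid()
  seg2$major_cn[seg2$chrom == "chr1"] <- 2L  # 100 of 240 Mb
  seg2 <- rbind(seg2[seg2$chrom != "chr2", ],
                data.frame(chrom = "chr2", start = 1, end = 20e6,
                           major_cn = 2L, minor_cn = 1L),
                data.frame(chrom = "chr2", start = 20000001, end = 80e6,
                           major_cn = 1L, minor_cn = 1L))
  expect_false(call_wgd(seg2, toy)$wgd)  # 120/240 = 0.5 exactly
})

test_that("coverage warning and annotation errors", {
  seg <- data.frame(chrom = "chr1", start = 1, end = 50e6,
                    major_cn = 1L, minor_cn = 1L)
  expect_warning(scar_scores(seg, toy), "90%")
  seg_bad <- rbind(diploid(),
                   data.frame(chrom = "chr4", start = 1, end = 1e6,
                              major_cn = 1L, minor_cn = 1L))
  expect_error(scar_scores(seg_bad, toy), "missing arm annotation")
  # non-numeric contigs are ignored, not an error
  seg_x <- rbind(diploid(),
                 data.frame(chrom = "chrX", start = 1, end = 1e6,
                            major_cn = 1L, minor_cn = 1L))
  expect_silent(scar_scores(seg_x, toy))
})
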