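# simulate: synthetic cohort generator with ground truth, and the
# Galton-Watson growth model with dissemination.

test_that("clone tree shape and determinism", {
  ct <- simulate_clone_tree(5, seed = 2)
  expect_equal(ct$parent[1], 0L)
  expect_true(all(ct$parent[-1] < seq_along(ct$parent)[-1]))  # parents earlier
  expect_equal(sort(unique(ct$mutations$clone)) %in% 1:5, rep(TRUE,
    length(unique(ct$mutations$clone))))
  expect_identical(simulate_clone_tree(5, seed = 2), ct)
  expect_error(simulate_clone_tree(0), ">= 1")
})

test_that("subtree CCF accumulates descendant clone fractions", {
  # chain 1 -> 2 -> 3 plus a sibling 4 of 2
  parent <- c(0L, 1L, 2L, 1L)
  frac <- c(0.4, 0.3, 0.2, 0.1)
  ccf <- mrsevo:::subtree_ccf(parent, frac)
  expect_equal(ccf, c(1.0, 0.5, 0.2, 0.1))
})

test_that("expected VAF inverts exactly through compute_ccf (noiseless)", {
  rho <- 0.7
  for (ccf_true in c(1, 0.6, 0.25)) {
    for (cn in list(c(1L, 1L), c(2L, 1L))) {
      cnt <- sum(cn)
      evaf <- expected_vaf(ccf_true, rho, cnt, 1)
      depth <- 1e6  # noiseless: exact counts
      v <- make_variants(1, chrom = "chr1", pos = 100L,
                         alt_count = as.integer(round(evaf * depth)))
      v$ref_count <- depth - v$alt_count
      seg <- data.frame(chrom = "chr1", start = 1L, end = 1000L,
                        major_cn = cn[1], minor_cn = cn[2])
      out <- compute_ccf(v, purity = rho, segments = seg)
      expect_equal(out$ccf, ccf_true, tolerance = 1e-5)
    }
  }
})

test_that("cohort generator is deterministic and internally consistent", {
  co <- simulate_multiregion_cohort(seed = 3)
  co2 <- simulate_multiregion_cohort(seed = 3)
  expect_identical(co, co2)
  expect_equal(length(unique(co$sheet$patient_id)), 10)
  expect_equal(sum(tapply(co$sheet$group, co$sheet$patient_id,
                          function(g) g[1]) == "Mut"), 7)
  expect_setequal(names(co$variants), co$sheet$sample_id)
  expect_setequal(names(co$segments), co$sheet$sample_id)
  # purity range respected
  expect_true(all(co$sheet$purity >= 0.3 & co$sheet$purity <= 0.9))
  # every patient has >= 1 primary and >= 1 metastatic sample
  by_pat <- split(co$sheet$site, co$sheet$patient_id)
  expect_true(all(vapply(by_pat, function(s)
    any(s == "primary") && any(s != "primary"), logical(1))))
})

test_that("clone fractions sum to 1 and truth CCFs lie in [0, 1]", {
  co <- simulate_multiregion_cohort(seed = 4)
  for (t in co$truth) {
    expect_equal(unname(rowSums(t$clone_fractions)),
                 rep(1, nrow(t$clone_fractions)), tolerance = 1e-9)
    expect_true(all(t$ccf >= 0 & t$ccf <= 1 + 1e-9))
    # truncal mutations are clonal everywhere
    trunk_muts <- t$mutations$mut_id[t$mutations$clone == 1]
    expect_true(all(t$ccf[trunk_muts, ] == 1))
  }
})

test_that("Mut patients carry trunk MEN1/DAXX; WT patients do not", {
  co <- simulate_multiregion_cohort(seed = 5)
  groups <- vapply(split(co$sheet$group, co$sheet$patient_id), `[`, "", 1)
  for (pid in names(co$truth)) {
    genes <- co$truth[[pid]]$mutations$gene
    if (groups[pid] == "Mut") {
      expect_true(all(c("MEN1", "DAXX") %in% genes))
      expect_true("MSEL1" %in% genes)
    } else {
      expect_false(any(c("MEN1", "DAXX", "MSEL1") %in% genes))
    }
  }
})

test_that("planted metastasis-selected gene rides the seeding clone", {
  co <- simulate_multiregion_cohort(seed = 6)
  for (pid in names(co$truth)) {
    t <- co$truth[[pid]]
    msel <- t$mutations[t$mutations$gene == "MSEL1", ]
    if (nrow(msel) == 0) next
    expect_equal(msel$clone, t$seeding_clone)
    # subclonal (0.3) in at least one primary, clonal in >= 1 metastasis
    sheet <- co$sheet[co$sheet$patient_id == pid, ]
    ccf <- t$ccf[msel$mut_id, ]
    prim <- sheet$sample_id[sheet$site == "primary"]
    mets <- sheet$sample_id[sheet$site != "primary"]
    if (t$met_origin == "common") {
      expect_true(any(ccf[prim] > 0 & ccf[prim] < 0.85))
      expect_true(any(ccf[mets] >= 0.999))
    } else {
      expect_true(all(ccf[prim] == 0))
      expect_true(all(ccf[mets] >= 0.999))
    }
  }
})

test_that("write_cohort round-trips through the io readers", {
  co <- simulate_multiregion_cohort(cohort_config(n_patients = 2), seed = 8)
  dir <- tempfile()
  write_cohort(co, dir)
  v <- read_variant_table(file.path(dir, "variants.maf"))
  expect_setequal(names(v), names(co$variants))
  some <- names(v)[1]
  expect_equal(v[[some]]$pos, co$variants[[some]]$pos)
  seg <- read_segments(file.path(dir, "segments.seg"))
  expect_setequal(names(seg), names(co$segments))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(sheet$sample_id, co$sheet$sample_id)
})

test_that("growth params validate and classify threshold correctly", {
  expect_error(growth_params(u = 0), "u must be")
  expect_error(growth_params(Nd = 1e10), "Nd must lie")
  p <- growth_params()
  expect_equal(p$early_threshold, 1e8)
  expect_equal(p$birth_prob, 0.55)
})

test_that("growth simulation output is well-formed and deterministic", {
  p <- growth_params(u = 1, Nd = 1e4, n_exact = 500)
  a <- simulate_growth_with_dissemination(p, seed = 11)
  b <- simulate_growth_with_dissemination(p, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$primary$ccf >= p$detect_floor & a$primary$ccf <= 1))
  expect_true(all(a$met$ccf >= p$detect_floor & a$met$ccf <= 1))
  expect_equal(anyDuplicated(a$primary$mut_id), 0)
  expect_equal(anyDuplicated(a$met$mut_id), 0)
})

test_that("seeding-lineage mutations are clonal in the metastasis", {
  p <- growth_params(u = 2, Nd = 1e5)
  sim <- simulate_growth_with_dissemination(p, seed = 13)
  seed_ids <- grep("^m[0-9]", sim$met$mut_id, value = TRUE)
  expect_true(all(sim$met$ccf[sim$met$mut_id %in% seed_ids] == 1))
})

test_that("met-private clonal mutations increase with dissemination size", {
  # the timing signal: a later (larger Nd) seed has accumulated more
  # private divisions, so more mutations are clonal in the metastasis
  # but absent from the primary's detectable set
  stat_at <- function(nd, seeds) {
    vapply(seeds, function(sd) {
      sim <- simulate_growth_with_dissemination(
        growth_params(u = 1, Nd = nd), seed = sd)
      pair_summary_stats(ccf_to_pair_input(sim$primary),
                         ccf_to_pair_input(sim$met))$n_met_private_clonal
    }, numeric(1))
  }
  lo <- mean(stat_at(1e4, 1:6))
  hi <- mean(stat_at(1e9, 1:6))
  expect_gt(hi, lo)
})
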