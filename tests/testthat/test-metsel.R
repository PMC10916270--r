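# metastasis_selection: pair enumeration, event detection, gene
# aggregation with the 60% rule, and the Mut/WT Fisher comparison.

test_that("pair enumeration is the primary x metastasis product", {
  sheet <- data.frame(
    sample_id = c("PT1", "PT2", "PT3", "LN1", "LI1"),
    patient_id = "P1",
    site = c("primary", "primary", "primary", "lymph_node", "liver"))
  pairs <- enumerate_pairs(sheet)
  expect_equal(nrow(pairs), 6)  # 3 x 2
  # counting oracle on random fixtures
  set.seed(2)
  for (rep in 1:5) {
    np <- sample(1:4, 1); nm <- sample(1:3, 1)
    sh <- data.frame(
      sample_id = paste0("S", seq_len(np + nm)), patient_id = "P",
      site = c(rep("primary", np),
               sample(c("lymph_node", "liver"), nm, replace = TRUE)))
    expect_equal(nrow(enumerate_pairs(sh)), np * nm)
  }
  # no metastasis -> empty with warning; no primary -> error
  expect_warning(p0 <- enumerate_pairs(
    data.frame(sample_id = "PT1", patient_id = "P1", site = "primary")),
    "no metastatic")
  expect_equal(nrow(p0), 0)
  expect_error(suppressWarnings(enumerate_pairs(
    data.frame(sample_id = "LN1", patient_id = "P1", site = "lymph_node"))),
    "no primary")
})

# small helper: clonality-labelled variant frames for pair tests
labelled <- function(n, clonality, offset = 0L) {
  v <- make_variants(n)
  v$pos <- v$pos + offset
  v$clonality <- rep_len(clonality, n)
  v
}

test_that("event detection implements the two rules exactly", {
  primary <- labelled(3, c("clonal", "subclonal", "subclonal"))
  # met carries variants 1 (clonal), 2 (clonal: sweep), plus a new one
  met <- rbind(labelled(2, "clonal"), labelled(1, "clonal", offset = 9000L))
  ev <- detect_pair_events(primary, met)
  expect_setequal(ev$category, c("subclonal_to_clonal", "met_exclusive"))
  expect_equal(ev$category[ev$key == "chr1:2000:C:T"], "subclonal_to_clonal")
  expect_equal(ev$category[ev$key == "chr1:10000:C:T"], "met_exclusive")
  # clonal in both (variant 1) and primary-only (variant 3): no events
  expect_equal(nrow(ev), 2)
})

test_that("subclonal met variants yield no subclonal_to_clonal event", {
  primary <- labelled(1, "subclonal")
  met <- labelled(1, "subclonal")
  expect_equal(nrow(detect_pair_events(primary, met)), 0)
})

test_that("60% aggregation rule and Fisher comparison", {
  # 7 Mut + 3 WT patients; gene A in 5/7 Mut (0.714 retained),
  # gene B in 4/7 Mut (0.571 dropped), gene C in 2/3 WT (0.667 retained)
  ev <- function(genes) data.frame(
    key = paste0("k", seq_along(genes), recycle0 = TRUE), gene = genes,
    category = rep("met_exclusive", length(genes)),
    stringsAsFactors = FALSE)
  events <- c(
    lapply(1:5, function(i) ev(c("A", "B")[c(TRUE, i <= 4)])),
    lapply(6:7, function(i) ev(character(0))),
    lapply(1:2, function(i) ev("C")),
    list(ev(character(0))))
  names(events) <- paste0("P", 1:10)
  groups <- stats::setNames(rep(c("Mut", "WT"), c(7, 3)), names(events))
  agg <- aggregate_events(events, groups)
  expect_true(agg$retained[agg$gene == "A"])
  expect_false(agg$retained[agg$gene == "B"])
  expect_true(agg$retained[agg$gene == "C"])
  expect_equal(agg$frac_mut[agg$gene == "A"], 5 / 7, tolerance = 1e-12)

  cmp <- compare_event_groups(agg, 7, 3)
  expect_setequal(cmp$gene, c("A", "C"))
  # oracle: fisher.test on the same tables
  pa <- stats::fisher.test(matrix(c(5, 2, 0, 3), 2))$p.value
  expect_equal(cmp$fisher_p[cmp$gene == "A"], pa)
  expect_equal(cmp$fdr, stats::p.adjust(cmp$fisher_p, "BH"))
})

test_that("the worked 7-0 vs 0-3 table gives p = 1/C(10,7)", {
  agg <- data.frame(gene = "X", n_mut = 7, n_wt = 0, frac_mut = 1,
                    frac_wt = 0, retained = TRUE)
  cmp <- compare_event_groups(agg, 7, 3)
  expect_equal(cmp$fisher_p, 1 / choose(10, 7), tolerance = 1e-12)
})

test_that("aggregate_events rejects an empty group and empty events", {
  events <- list(P1 = data.frame(key = "k", gene = "A", category = "met_exclusive"))
  expect_error(aggregate_events(events, c(P1 = "Mut")), "empty")
  ev0 <- list(P1 = data.frame(key = character(0), gene = character(0),
                              category = character(0)),
              P2 = data.frame(key = character(0), gene = character(0),
                              category = character(0)))
  agg <- aggregate_events(ev0, c(P1 = "Mut", P2 = "WT"))
  expect_equal(nrow(agg), 0)
  cmp <- compare_event_groups(agg, 1, 1)
  expect_equal(nrow(cmp), 0)
})

test_that("event detection is monotone in the clonality cutoff", {
  # raising the cutoff can only move primary variants clonal->subclonal
  # and met variants clonal->subclonal; a variant that is an event at the
  # low cutoff because it is subclonal-in-primary stays subclonal at the
  # higher cutoff, so losing its event requires losing met clonality --
  # both transitions cannot *create* a new s2c event pair
  set.seed(9)
  v <- make_variants(30)
  ccf_p <- stats::runif(30); ccf_m <- stats::runif(30)
  lab <- function(ccf, cut) ifelse(ccf >= cut, "clonal", "subclonal")
  for (pair in list(c(0.7, 0.9))) {
    lo <- pair[1]; hi <- pair[2]
    p_lo <- v; p_lo$clonality <- lab(ccf_p, lo)
    m_lo <- v; m_lo$clonality <- lab(ccf_m, lo)
    p_hi <- v; p_hi$clonality <- lab(ccf_p, hi)
    m_hi <- v; m_hi$clonality <- lab(ccf_m, hi)
    ev_lo <- detect_pair_events(p_lo, m_lo)
    ev_hi <- detect_pair_events(p_hi, m_hi)
    s2c_hi <- ev_hi$key[ev_hi$category == "subclonal_to_clonal"]
    s2c_lo <- ev_lo$key[ev_lo$category == "subclonal_to_clonal"]
    # any new s2c event at the high cutoff must come from a variant that
    # was clonal in the primary at the low cutoff (not newly created by
    # the met side, which only loses clonal labels)
    new <- setdiff(s2c_hi, s2c_lo)
    from_primary_demotion <- v$pos[lab(ccf_p, lo) == "clonal" &
                                   lab(ccf_p, hi) == "subclonal"]
    expect_true(all(new %in% paste0("chr1:", from_primary_demotion, ":C:T")))
  }
})

test_that("end-to-end met_selection_analysis finds the planted gene", {
  co <- simulate_multiregion_cohort(seed = 1)
  pr <- process_cohort(co)
  ms <- met_selection_analysis(pr)
  row <- ms$compared[ms$compared$gene == "MSEL1", ]
  expect_equal(nrow(row), 1)
  expect_true(row$significant)
  expect_equal(row$frac_mut, 1)
  expect_equal(row$n_wt, 0)
})
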