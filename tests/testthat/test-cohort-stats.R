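# cohort_stats: group assignment, Mann-Whitney / Fisher / BH against
# independent oracles, Kaplan-Meier + log-rank, the cBioPortal-format
# adapter, and the per-metric per-site group report.

test_that("assign_groups requires a nonsynonymous driver hit", {
  mk <- function(gene, class) {
    v <- make_variants(1)
    v$gene <- gene; v$variant_class <- class
    v
  }
  cohort <- list(
    P1 = list(S1 = mk("MEN1", "missense")),
    P2 = list(S1 = mk("MEN1", "silent")),          # synonymous: WT
    P3 = list(S1 = mk("KRAS", "missense")),        # off-panel: WT
    P4 = list(S1 = mk("TP53", "silent"), S2 = mk("DAXX", "frameshift_indel")))
  g <- assign_groups(cohort)
  expect_equal(unname(g), c("Mut", "WT", "WT", "Mut"))
  expect_equal(names(g), c("P1", "P2", "P3", "P4"))
  expect_error(assign_groups(cohort, character(0)), "empty gene set")
})

test_that("Mann-Whitney exact p matches full permutation enumeration", {
  # enumeration oracle: distribution of U over all assignments of the
  # pooled values to the two groups (small n, no ties -> exact)
  set.seed(23)
  for (rep in 1:4) {
    nx <- sample(3:4, 1); ny <- sample(3:4, 1)
    pooled <- sample(100, nx + ny)  # distinct -> no ties
    x <- pooled[1:nx]; y <- pooled[-(1:nx)]
    got <- mann_whitney(x, y)
    u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    expect_equal(got$U, u_of(x, y))
    combs <- utils::combn(nx + ny, nx)
    u_all <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
    mu <- nx * ny / 2
    p_exact <- mean(abs(u_all - mu) >= abs(got$U - mu))
    expect_equal(got$p, p_exact, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  set.seed(29)
  for (rep in 1:5) {
    tab <- matrix(sample(0:8, 4, TRUE), 2)
    got <- fisher_exact(tab)
    # oracle: conditional on margins, sum hypergeometric probabilities
    # of all tables at most as probable as the observed one
    m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
    a_range <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(a_range, m, n, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n, k)
    p_oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(got$p, p_oracle, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("BH adjustment: worked example and step-up formula oracle", {
  # all of {0.01, 0.02, 0.03, 0.04} adjust to 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(31)
  p <- stats::runif(12)
  got <- bh_adjust(p)
  m <- length(p); o <- order(p)
  stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- numeric(m); oracle[o] <- pmin(stepup, 1)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Kaplan-Meier medians use the smallest time with S <= 0.5", {
  # group A: events at 1,2,3,4 -> S hits 0.5 at t=2; group B: no events
  times <- c(1, 2, 3, 4, 5, 6, 7)
  events <- c(1, 1, 1, 1, 0, 0, 0)
  groups <- c(rep("A", 4), rep("B", 3))
  km <- km_logrank(times, events, groups)
  expect_equal(unname(km$median["A"]), 2)
  expect_true(is.na(km$median["B"]))  # median not reached
  # log-rank oracle via survdiff
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  expect_equal(km$chisq, sd$chisq)
  expect_equal(km$p, stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
})

test_that("KM survival probabilities match the product-limit formula", {
  # one group, hand-computable: n=5, events at 2 and 5, censored at 3
  times <- c(2, 3, 5, 6, 7)
  events <- c(1, 0, 1, 0, 0)
  km <- km_logrank(c(times, 10), c(events, 1), c(rep("A", 5), "B"))
  a <- km$curves[km$curves$group == "A", ]
  expect_equal(a$surv[a$time == 2], 4 / 5)
  expect_equal(a$surv[a$time == 5], 4 / 5 * 2 / 3)
})

test_that("km_logrank handles no events and validates input", {
  expect_warning(km <- km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0),
                                  c("A", "A", "B", "B")), "no events")
  expect_equal(km$p, 1)
  expect_true(is.na(km$chisq))
  expect_error(km_logrank(1:3, c(1, 1, 1), c("A", "A", "A")),
               "at least one")
})

# (write_cbio_fixture lives in helper-fixtures.R)

test_that("msk_met_adapter joins, derives columns and filters", {
  fx <- write_cbio_fixture()
  ad <- msk_met_adapter(fx$clinical, fx$mutations)
  # P3 has no mutations and CNA_COUNT 0 -> excluded
  expect_equal(ad$clinical$PATIENT_ID, c("P-0000001", "P-0000002"))
  expect_equal(ad$n_excluded, 1)
  expect_equal(ad$clinical$n_mutations, c(2, 1))
  expect_setequal(ad$clinical$mutated_genes[[1]], c("MEN1", "TP53"))
  expect_equal(ad$clinical$TMB, c(7.5, 2.0))
  expect_equal(ad$clinical$MSI, c(0.2, 0.1))
  expect_equal(ad$clinical$os_event, c(1L, 0L))
  g <- adapter_groups(ad)
  expect_equal(g, c("Mut", "WT"))
})

test_that("msk_met_adapter validates required columns", {
  dir <- tempfile(); dir.create(dir)
  bad <- file.path(dir, "bad.txt")
  writeLines("SOMETHING_ELSE\tTMB\nX\t1", bad)
  fx <- write_cbio_fixture()
  expect_error(msk_met_adapter(bad, fx$mutations), "PATIENT_ID")
  badmut <- file.path(dir, "badmut.txt")
  writeLines("Hugo_Symbol\nMEN1", badmut)
  expect_error(msk_met_adapter(fx$clinical, badmut),
               "PATIENT_ID / Tumor_Sample_Barcode")
})

test_that("group_report dispatches tests by metric type and adjusts", {
  set.seed(41)
  metrics <- data.frame(
    group = rep(c("Mut", "WT"), each = 6),
    site = rep(rep(c("primary", "liver"), each = 3), 2),
    tmb = c(stats::rnorm(6, 10), stats::rnorm(6, 2)),
    wgd = c(rep(TRUE, 5), rep(FALSE, 7)))
  rep_out <- group_report(metrics, c("tmb", "wgd"))
  expect_equal(nrow(rep_out), 4)  # 2 metrics x 2 strata
  expect_false(any(rep_out$skipped))
  # oracle each row
  for (i in seq_len(nrow(rep_out))) {
    d <- metrics[metrics$site == rep_out$stratum[i], ]
    x <- d[[rep_out$metric[i]]][d$group == "Mut"]
    y <- d[[rep_out$metric[i]]][d$group == "WT"]
    p_o <- if (is.logical(d[[rep_out$metric[i]]])) {
      stats::fisher.test(matrix(c(sum(x), sum(!x), sum(y), sum(!y)), 2))$p.value
    } else suppressWarnings(stats::wilcox.test(x, y)$p.value)
    expect_equal(rep_out$p[i], p_o)
  }
  expect_equal(rep_out$fdr, stats::p.adjust(rep_out$p, "BH"))
})

test_that("group_report flags strata with an empty group", {
  metrics <- data.frame(
    group = c("Mut", "Mut", "WT"),
    site = c("liver", "primary", "primary"),
    tmb = c(5, 6, 1))
  out <- group_report(metrics, "tmb")
  expect_true(out$skipped[out$stratum == "liver"])
  expect_false(out$skipped[out$stratum == "primary"])
  expect_true(is.na(out$p[out$stratum == "liver"]))
  expect_true(is.na(out$fdr[out$stratum == "liver"]))
})
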