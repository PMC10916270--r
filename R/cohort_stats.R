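# Cohort-level statistics: Mut/WT group assignment from a driver gene
# set, Mann-Whitney and Fisher comparisons with Benjamini-Hochberg
# correction, Kaplan-Meier survival with the log-rank test, an adapter
# for cBioPortal-format clinical + mutation tables, and the per-metric,
# per-site group report.

NONSYNONYMOUS_CLASSES <- c("missense", "nonsense", "nonstop",
                           "frameshift_indel", "inframe_indel",
                           "splice_site")

#' Assign Mut/WT group labels from a driver gene set
#'
#' A patient is `Mut` when any retained nonsynonymous variant in the gene
#' set occurs in any of the patient's samples.
#'
#' @param cohort_variants Named list (patient) of named lists (sample) of
#'   retained variant data frames.
#' @param gene_set Character vector of driver genes (default MEN1, DAXX).
#' @return Named character vector patient -> `"Mut"`/`"WT"`.
#' @export
assign_groups <- function(cohort_variants, gene_set = c("MEN1", "DAXX")) {
  if (length(gene_set) == 0) stop("empty gene set")
  vapply(cohort_variants, function(samples) {
    hit <- any(vapply(samples, function(v)
      any(v$gene %in% gene_set &
          v$variant_class %in% NONSYNONYMOUS_CLASSES), logical(1)))
    if (hit) "Mut" else "WT"
  }, character(1))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. Exact when
#' feasible (small samples without ties), otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return List with `odds_ratio` and two-sided `p`.
#' @export
fisher_exact <- function(table) {
  if (any(table < 0)) stop("negative entry in contingency table")
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted values, in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit survival per group, the median survival time (smallest
#' time with S(t) <= 0.5, or `NA` = not reached), and the two-group
#' log-rank chi-square and p (1 df). When no events occur anywhere the
#' log-rank test is undefined and p = 1 is reported with a warning.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (two levels).
#' @return List with `curves` (data frame time/surv/n_risk/group),
#'   `median` (named per group), `chisq`, `p`.
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("each group needs at least one subject")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk,
                       group = sub("^groups=", "", strata),
                       stringsAsFactors = FALSE)
  med <- vapply(split(curves, curves$group), function(cv) {
    i <- which(cv$surv <= 0.5)
    if (length(i) == 0) NA_real_ else min(cv$time[i])
  }, numeric(1))
  if (sum(events) == 0) {
    warning("no events observed; log-rank test undefined, reporting p = 1")
    return(list(curves = curves, median = med, chisq = NA_real_, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, median = med, chisq = sd$chisq, p = p)
}

#' Adapter for cBioPortal-format clinical and mutation tables
#'
#' Joins a clinical table (patient id, TMB/MSI/OS columns) with a
#' mutation table (patient or sample id + gene) and restricts to tumors
#' exhibiting at least one mutation or copy-number event.
#'
#' @param clinical_path Tab-separated clinical file; `#`-prefixed header
#'   lines are skipped. Must contain a `PATIENT_ID` column; recognized
#'   value columns are `TMB_NONSYNONYMOUS` (or `TMB`), `MSI_SCORE` (or
#'   `MSI`), `OS_MONTHS`, `OS_STATUS`, `CNA_COUNT`.
#' @param mutations_path Tab-separated mutation file with
#'   `Hugo_Symbol` and `PATIENT_ID` (or `Tumor_Sample_Barcode`, from
#'   which the patient id is taken as the barcode's first two
#'   `-`-separated fields, the MSK impact-cohort convention of
#'   `P-XXXXXXX-TXX-IMX` sample barcodes under `P-XXXXXXX` patients).
#' @return List with `clinical` (joined per-patient data frame with
#'   `mutated_genes` list-column and `n_mutations`) filtered to patients
#'   with >= 1 mutation or CNV event.
#' @export
msk_met_adapter <- function(clinical_path, mutations_path) {
  read_cbio <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                      quote = "", check.names = TRUE,
                      stringsAsFactors = FALSE)
  }
  clin <- read_cbio(clinical_path)
  mut <- read_cbio(mutations_path)
  if (!"PATIENT_ID" %in% names(clin)) stop("clinical table lacks PATIENT_ID")
  if (!"PATIENT_ID" %in% names(mut)) {
    if (!"Tumor_Sample_Barcode" %in% names(mut))
      stop("mutation table lacks PATIENT_ID / Tumor_Sample_Barcode")
    mut$PATIENT_ID <- vapply(strsplit(mut$Tumor_Sample_Barcode, "-"),
                             function(x) paste(x[seq_len(min(2, length(x)))],
                                               collapse = "-"), "")
  }
  if (!"Hugo_Symbol" %in% names(mut)) stop("mutation table lacks Hugo_Symbol")
  genes <- split(mut$Hugo_Symbol, mut$PATIENT_ID)
  clin$mutated_genes <- unname(genes[clin$PATIENT_ID])
  clin$mutated_genes[vapply(clin$mutated_genes, is.null, logical(1))] <-
    list(character(0))
  clin$n_mutations <- lengths(clin$mutated_genes)
  if (!"TMB" %in% names(clin) && "TMB_NONSYNONYMOUS" %in% names(clin))
    clin$TMB <- as.numeric(clin$TMB_NONSYNONYMOUS)
  if (!"MSI" %in% names(clin) && "MSI_SCORE" %in% names(clin))
    clin$MSI <- as.numeric(clin$MSI_SCORE)
  if ("OS_STATUS" %in% names(clin))
    clin$os_event <- as.integer(grepl("^1|DECEASED", clin$OS_STATUS))
  cna <- if ("CNA_COUNT" %in% names(clin))
    as.numeric(clin$CNA_COUNT) else rep(0, nrow(clin))
  cna[is.na(cna)] <- 0
  keep <- clin$n_mutations > 0 | cna > 0
  list(clinical = clin[keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

#' Group labels for an adapter cohort
#'
#' @param adapter List from [msk_met_adapter()].
#' @param gene_set Driver gene set (default MEN1, DAXX, ATRX).
#' @return Character vector of `"Mut"`/`"WT"` per row of
#'   `adapter$clinical`.
#' @export
adapter_groups <- function(adapter, gene_set = c("MEN1", "DAXX", "ATRX")) {
  if (length(gene_set) == 0) stop("empty gene set")
  ifelse(vapply(adapter$clinical$mutated_genes,
                function(g) any(g %in% gene_set), logical(1)), "Mut", "WT")
}

#' Per-metric, per-site group comparison report
#'
#' For each metric column and site stratum, compares Mut vs WT samples
#' with the Mann-Whitney test (continuous metrics) or Fisher's exact
#' test (logical metrics such as WGD), then adjusts the whole table with
#' Benjamini-Hochberg. Strata where either group is empty are flagged
#' and skipped.
#'
#' @param metrics Data frame with one row per sample: a `group` column,
#'   a `site` column, and the metric columns named in `metric_cols`.
#' @param metric_cols Character vector of metric column names.
#' @return Data frame with one row per metric x stratum: `metric`,
#'   `stratum`, group means (or proportions), `statistic`, `p`, `fdr`,
#'   `skipped`.
#' @export
group_report <- function(metrics, metric_cols) {
  strata <- unique(metrics$site)
  rows <- list()
  for (m in metric_cols) {
    for (st in strata) {
      d <- metrics[metrics$site == st, , drop = FALSE]
      x <- d[[m]][d$group == "Mut"]; y <- d[[m]][d$group == "WT"]
      if (length(x) == 0 || length(y) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, stratum = st, mean_mut = NA_real_,
          mean_wt = NA_real_, statistic = NA_real_, p = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (is.logical(d[[m]])) {
        tab <- matrix(c(sum(x), sum(!x), sum(y), sum(!y)), 2)
        ft <- fisher_exact(tab)
        stat <- ft$odds_ratio; p <- ft$p
      } else {
        mw <- mann_whitney(x, y)
        stat <- mw$U; p <- mw$p
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, stratum = st, mean_mut = mean(as.numeric(x)),
        mean_wt = mean(as.numeric(y)), statistic = stat, p = p,
        skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  out$fdr[!out$skipped] <- bh_adjust(out$p[!out$skipped])
  rownames(out) <- NULL
  out
}
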