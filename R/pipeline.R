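# End-to-end orchestration over a cohort: purity exclusion, the filter
# cascade, CCF annotation and clonality per sample, and per-patient
# groupings consumed by the heterogeneity, phylogeny and
# metastasis-selection stages.

#' Run filtering and CCF annotation over a whole cohort
#'
#' Excludes low-purity samples, applies the variant filter cascade per
#' sample, and annotates retained variants with VAF, multiplicity, CCF
#' (with confidence interval) and the clonal/subclonal label.
#'
#' @param cohort List with `sheet`, `variants`, `segments` (as produced
#'   by [simulate_multiregion_cohort()] or assembled from
#'   [read_variant_table()], [read_segments()], [read_sample_sheet()]).
#' @param thresholds Filter thresholds ([filter_thresholds()]).
#' @return List with `sheet` (retained samples), `annotated` (named list
#'   of CCF-annotated retained-variant data frames), `rejected` (named
#'   list of rejected variants with reasons), and `by_patient` (named
#'   list of per-patient named sample lists).
#' @export
process_cohort <- function(cohort, thresholds = filter_thresholds()) {
  sheet <- exclude_low_purity(cohort$sheet, thresholds$min_purity)
  annotated <- list(); rejected <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    v <- cohort$variants[[sid]]
    if (is.null(v)) next
    flt <- apply_variant_filters(v, thresholds)
    ann <- compute_ccf(flt$retained, purity = sheet$purity[i],
                       segments = cohort$segments[[sid]])
    annotated[[sid]] <- classify_clonality(ann)
    rejected[[sid]] <- flt$rejected
  }
  by_patient <- lapply(split(sheet$sample_id, sheet$patient_id),
                       function(ids) annotated[ids])
  list(sheet = sheet, annotated = annotated, rejected = rejected,
       by_patient = by_patient)
}

#' Per-sample heterogeneity metrics table
#'
#' MATH score, TMB, clonal/subclonal counts per sample, joined with the
#' sample sheet (including any pass-through columns such as TNB or MSI).
#'
#' @param processed List from [process_cohort()].
#' @param panel_mb Capture panel size in Mb for TMB.
#' @return Data frame with one row per sample.
#' @export
sample_metrics <- function(processed, panel_mb = 30) {
  sheet <- processed$sheet
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    v <- processed$annotated[[sheet$sample_id[i]]]
    data.frame(
      sample_id = sheet$sample_id[i],
      math = if (nrow(v) >= 3 && stats::median(v$vaf) > 0)
        math_score(v$vaf) else NA_real_,
      tmb = tmb(v, panel_mb),
      n_clonal = sum(v$clonality == "clonal"),
      n_subclonal = sum(v$clonality == "subclonal"),
      stringsAsFactors = FALSE)
  })
  merge(sheet, do.call(rbind, rows), by = "sample_id", sort = FALSE)
}

#' Per-patient sharing summaries
#'
#' @param processed List from [process_cohort()].
#' @return Named list of [classify_sharing()] results (patients with
#'   >= 2 retained samples).
#' @export
cohort_sharing <- function(processed) {
  pats <- processed$by_patient[lengths(processed$by_patient) >= 2]
  lapply(pats, classify_sharing)
}

#' Metastasis-selected event analysis over a processed cohort
#'
#' Enumerates primary-metastasis pairs per patient, detects pair events,
#' aggregates them to gene level with the patient-prevalence rule, and
#' compares Mut vs WT event frequencies.
#'
#' @param processed List from [process_cohort()].
#' @param min_patient_frac Prevalence threshold (default 0.6).
#' @return List with `events_by_patient`, `aggregated`, `compared`.
#' @export
met_selection_analysis <- function(processed, min_patient_frac = 0.6) {
  sheet <- processed$sheet
  groups <- vapply(split(sheet$group, sheet$patient_id), `[`, "", 1)
  events_by_patient <- lapply(split(sheet, sheet$patient_id), function(ps) {
    pairs <- suppressWarnings(enumerate_pairs(ps))
    if (nrow(pairs) == 0) {
      return(data.frame(key = character(0), gene = character(0),
                        category = character(0)))
    }
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(j)
      detect_pair_events(processed$annotated[[pairs$primary[j]]],
                         processed$annotated[[pairs$met[j]]])))
  })
  agg <- aggregate_events(events_by_patient, groups, min_patient_frac)
  cmp <- compare_event_groups(agg, sum(groups == "Mut"),
                              sum(groups == "WT"))
  list(events_by_patient = events_by_patient, aggregated = agg,
       compared = cmp)
}

#' Per-patient phylogeny with metastatic-origin classification
#'
#' @param processed List from [process_cohort()].
#' @param patient_id Patient to analyse.
#' @param builder `"nj"` or `"mp"`.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Integer seed for the bootstrap.
#' @return List with `matrix`, `tree` and `met_origin`.
#' @export
patient_phylogeny <- function(processed, patient_id,
                              builder = c("nj", "mp"), bootstrap = 100,
                              seed = 1) {
  builder <- match.arg(builder)
  samples <- processed$by_patient[[patient_id]]
  if (is.null(samples)) stop("unknown patient: ", patient_id)
  mat <- binary_matrix(samples)
  tree <- if (bootstrap > 0) bootstrap_support(mat, builder, bootstrap, seed)
          else if (builder == "nj") nj_tree(mat) else mp_search(mat)
  sheet <- processed$sheet[processed$sheet$patient_id == patient_id, ]
  sites <- stats::setNames(sheet$site, sheet$sample_id)
  origin <- classify_met_origin(tree, sites)
  list(matrix = mat, tree = tree, met_origin = origin)
}
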