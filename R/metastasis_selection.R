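# Metastasis-selected event detection: pair each primary region with
# each metastasis sample, flag variants exclusively present in the
# metastasis or rising from subclonal (primary) to clonal (metastasis),
# aggregate to gene level with a 60% patient-prevalence rule, and
# compare event frequencies between the Mut and WT groups.

#' Enumerate primary-metastasis sample pairs of one patient
#'
#' The Cartesian product of the patient's primary regions and metastatic
#' (lymph node + liver) samples.
#'
#' @param sheet Sample-sheet rows of one patient.
#' @return Data frame with columns `primary`, `met` (possibly 0 rows,
#'   with a warning when the patient has no metastatic sample).
#' @export
enumerate_pairs <- function(sheet) {
  prim <- sheet$sample_id[sheet$site == "primary"]
  met <- sheet$sample_id[sheet$site %in% c("lymph_node", "liver")]
  if (length(met) == 0) {
    warning("patient ", sheet$patient_id[1], " has no metastatic sample")
    return(data.frame(primary = character(0), met = character(0)))
  }
  if (length(prim) == 0) stop("patient has no primary sample")
  expand.grid(primary = prim, met = met, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' Detect metastasis-selected events in one sample pair
#'
#' Per variant: `met_exclusive` when retained in the metastasis and
#' absent from the primary; `subclonal_to_clonal` when subclonal in the
#' primary and clonal in the metastasis. Variants clonal in both or
#' absent from the metastasis yield no event.
#'
#' @param primary,met CCF-annotated, clonality-labelled variant data
#'   frames ([classify_clonality()] output) of the paired samples.
#' @return Data frame with `key`, `gene`, `category`.
#' @export
detect_pair_events <- function(primary, met) {
  pk <- variant_key(primary); mk <- variant_key(met)
  excl <- !mk %in% pk
  p_sub <- pk[primary$clonality == "subclonal"]
  s2c <- mk %in% p_sub & met$clonality == "clonal"
  out <- rbind(
    data.frame(key = mk[excl], gene = met$gene[excl],
               category = rep("met_exclusive", sum(excl)),
               stringsAsFactors = FALSE),
    data.frame(key = mk[s2c], gene = met$gene[s2c],
               category = rep("subclonal_to_clonal", sum(s2c)),
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Aggregate pair events to genes with the patient-prevalence rule
#'
#' A patient supports a gene when any of its primary-metastasis pairs
#' shows an event in that gene; genes are retained when supported by at
#' least `min_patient_frac` of the patients in the Mut group or in the
#' WT group.
#'
#' @param events_by_patient Named list (patient id) of event data frames
#'   from [detect_pair_events()], rows pooled over the patient's pairs.
#' @param groups Named character vector patient id -> `"Mut"`/`"WT"`.
#' @param min_patient_frac Prevalence threshold (default 0.6).
#' @return Data frame: gene, n_mut/n_wt supporting patients, group
#'   fractions, retained flag.
#' @export
aggregate_events <- function(events_by_patient, groups,
                             min_patient_frac = 0.6) {
  groups <- groups[names(events_by_patient)]
  n_mut_pat <- sum(groups == "Mut"); n_wt_pat <- sum(groups == "WT")
  if (n_mut_pat == 0 || n_wt_pat == 0) stop("empty patient group")
  support <- lapply(events_by_patient, function(ev) unique(ev$gene))
  genes <- sort(unique(unlist(support, use.names = FALSE)))
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), n_mut = integer(0),
                      n_wt = integer(0), frac_mut = numeric(0),
                      frac_wt = numeric(0), retained = logical(0)))
  }
  has <- vapply(support, function(g) genes %in% g, logical(length(genes)))
  has <- matrix(has, nrow = length(genes))
  n_mut <- rowSums(has[, groups == "Mut", drop = FALSE])
  n_wt <- rowSums(has[, groups == "WT", drop = FALSE])
  frac_mut <- n_mut / n_mut_pat
  frac_wt <- n_wt / n_wt_pat
  data.frame(gene = genes, n_mut = n_mut, n_wt = n_wt,
             frac_mut = frac_mut, frac_wt = frac_wt,
             retained = frac_mut >= min_patient_frac |
                        frac_wt >= min_patient_frac,
             stringsAsFactors = FALSE)
}

#' Compare metastasis-selected event frequencies between groups
#'
#' Per retained gene, a two-sided Fisher exact test on the 2x2 table of
#' patients with/without the event by Mut/WT group, with
#' Benjamini-Hochberg adjustment across retained genes.
#'
#' @param agg Data frame from [aggregate_events()].
#' @param n_mut_patients,n_wt_patients Group sizes.
#' @param fdr_cutoff Significance level on the adjusted p (default 0.05).
#' @return `agg` restricted to retained genes with `fisher_p`, `fdr` and
#'   `significant` columns.
#' @export
compare_event_groups <- function(agg, n_mut_patients, n_wt_patients,
                                 fdr_cutoff = 0.05) {
  ev <- agg[agg$retained, , drop = FALSE]
  if (nrow(ev) == 0) {
    ev$fisher_p <- numeric(0); ev$fdr <- numeric(0)
    ev$significant <- logical(0)
    return(ev)
  }
  ev$fisher_p <- vapply(seq_len(nrow(ev)), function(i) {
    tab <- matrix(c(ev$n_mut[i], n_mut_patients - ev$n_mut[i],
                    ev$n_wt[i], n_wt_patients - ev$n_wt[i]), 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  ev$fdr <- stats::p.adjust(ev$fisher_p, method = "BH")
  ev$significant <- ev$fdr < fdr_cutoff
  rownames(ev) <- NULL
  ev
}
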