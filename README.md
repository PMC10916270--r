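# mrsevo

Multiregion tumor evolution analysis for metastatic neuroendocrine
tumors: an R package plus a numbered analysis workflow.

Multiregion whole-exome sequencing (several spatially separated
specimens per tumor, each sequenced) makes it possible to ask how a
metastatic cancer evolved: which mutations are truncal versus
region-private, whether metastases arise from one primary sub-lineage
or several, which genes are selected during metastatic spread, and how
large the primary tumor was when it seeded each metastasis. `mrsevo`
implements that analysis end to end:

- **Variant filtering** — binomial-test calling against the sequencing
  error rate and a filter cascade (depth ≥ 30, ≥ 4 alt reads,
  VAF > 3%, indels ≤ 40 bp, population allele frequency < 1%, strand
  bias), with per-variant rejection reasons.
- **CCF and clonality** — cancer cell fraction from VAF, purity and
  allele-specific copy number with multiplicity estimation and
  Clopper–Pearson confidence propagation; clonal/subclonal labels.
- **Heterogeneity statistics** — MATH score, TMB over the qualifying
  nonsynonymous classes, public/shared/private sharing classes and the
  spatial-heterogeneity fraction.
- **Genomic scars** — HRD-LOH, telomeric allelic imbalance (TAI),
  large-scale state transitions (LST), length-weighted ploidy and the
  whole-genome duplication call.
- **Mutational signatures** — 96-channel catalogs, de novo NMF with
  cophenetic rank selection, cosine matching and NNLS exposure
  fitting.
- **Phylogenies** — binary mutation matrices with a germline outgroup,
  neighbor joining and maximum parsimony (exhaustive or NNI search,
  Fitch scoring), bootstrap supports, and a metastatic-origin
  classification (common vs distinct seeding lineage) per site.
- **Metastasis-selected events** — primary–metastasis pair events
  (met-exclusive, subclonal-to-clonal), a ≥ 60% patient-prevalence
  rule, and Mut-vs-WT Fisher comparison with BH correction.
- **Dissemination timing** — a Galton–Watson growth-with-dissemination
  simulator and rejection ABC over mutation rate `u` and dissemination
  size `Nd`, calling seeding early when posterior mass below 10⁸ cells
  exceeds one half.
- **Cohort statistics** — Mann–Whitney, Fisher, BH, Kaplan–Meier with
  log-rank, a per-metric per-site group report, and an adapter for
  cBioPortal-format clinical + mutation tables.

Because the study design this targets deposited no patient data, the
package ships a **synthetic cohort generator** with full clonal ground
truth (clone trees, per-sample clone fractions, planted driver and
metastasis-selected genes, planted seeding structure and dissemination
sizes), and the test suite validates every stage against that truth or
against independent oracle implementations.

## Worked example

```r
library(mrsevo)

cohort <- simulate_multiregion_cohort(seed = 1)
head(cohort$sheet[, c("sample_id", "patient_id", "site", "purity", "group")], 4)
#>   sample_id patient_id    site    purity group
#> 1   P01_PT1        P01 primary 0.5508450   Mut
#> 2   P01_PT2        P01 primary 0.4947986   Mut
#> 3   P01_PT3        P01 primary 0.7594723   Mut
#> 4   P01_PT4        P01 primary 0.7227933   Mut

processed <- process_cohort(cohort)   # filters + CCF + clonality
head(processed$annotated[["P01_PT1"]][, c("gene", "vaf", "ccf", "clonality")], 4)
#>        gene   vaf       ccf clonality
#> 1     MSEL1 0.085 0.3086168 subclonal
#> 2 GENE08053 0.285 1.0347738    clonal
#> 3 GENE03553 0.270 0.9803120    clonal
#> 4 GENE00935 0.290 1.0529277    clonal

# the planted metastasis-selected gene is recovered at FDR < 0.05
ms <- met_selection_analysis(processed)
ms$compared[ms$compared$significant, c("gene", "n_mut", "n_wt", "fisher_p", "fdr")]
#>    gene n_mut n_wt    fisher_p         fdr
#> 1 MSEL1     7    0 0.008333333 0.008333333

# per-patient phylogeny and metastatic-origin classification
ph <- patient_phylogeny(processed, "P01", builder = "nj", bootstrap = 100, seed = 1)
ph$met_origin
#> lymph_node      liver
#>   "common"   "common"

# worked heterogeneity formula
math_score(c(0.2, 0.3, 0.4))
#> [1] 49.42
```

## Analysis workflow

The `analysis/` directory holds numbered driver scripts that run the
pipeline on the synthetic cohort and write tab-separated results under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1      # cohort + ground truth seed
Rscript analysis/02_call_and_filter.R        # filters, CCF, clonality
Rscript analysis/03_heterogeneity.R          # MATH, TMB, sharing classes
Rscript analysis/04_cnv_metrics.R            # LOH/TAI/LST, ploidy, WGD
Rscript analysis/05_signatures.R             # catalogs, NMF, matching
Rscript analysis/06_phylogeny.R              # NJ + bootstrap, met origin
Rscript analysis/07_metastasis_selection.R   # pair events, Mut vs WT
Rscript analysis/08_dissemination_timing.R   # ABC early/late calls
Rscript analysis/09_cohort_stats.R           # group report, survival
```

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "mrsevo",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`scripts/acceptance.R` runs the full pipeline on synthetic data and
writes the main computed quantities (worked-formula values, CCF and
clonality recovery against ground truth, planted-gene detection,
metastatic-origin accuracy, NMF recovery, ABC timing calls, null
calibration) as JSON. The test suite includes `test-acceptance.R`,
one test per acceptance criterion, alongside per-module suites with
dual-route oracle checks.

See the vignette (`vignettes/multiregion-evolution.Rmd`) for the
methods in detail.
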