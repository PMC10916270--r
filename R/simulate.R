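# Synthetic multiregion cohort generation with full clonal ground truth,
# and a branching-process growth model with dissemination that supplies
# the timing signal for the ABC module. Every downstream stage of the
# pipeline can be validated against the truth objects produced here.

#' Simulate a random clone tree with branch mutations
#'
#' Builds a rooted random tree of `n_clones` clones (clone 1 is the
#' trunk; each later clone attaches to a uniformly chosen earlier clone)
#' and draws Poisson(`mutations_per_branch_mean`) mutation templates on
#' each branch.
#'
#' @param n_clones Number of clones (>= 1).
#' @param mutations_per_branch_mean Poisson mean of mutations per branch.
#' @param seed Integer seed; output is deterministic given it.
#' @param genome Arm annotation giving chromosome names and lengths for
#'   mutation placement.
#' @return List with `parent` (integer vector, 0 for the trunk) and
#'   `mutations` (data frame of variant templates with a `clone` column).
#' @export
simulate_clone_tree <- function(n_clones, mutations_per_branch_mean = 20,
                                seed = 1, genome = genome_arms("toy")) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  set.seed(seed)
  parent <- integer(n_clones)
  if (n_clones > 1) {
    for (i in 2:n_clones) parent[i] <- sample.int(i - 1, 1)
  }
  n_mut <- stats::rpois(n_clones, mutations_per_branch_mean)
  muts <- random_mutation_templates(sum(n_mut), genome)
  muts$clone <- rep(seq_len(n_clones), n_mut)
  list(parent = parent, n_clones = n_clones, mutations = muts)
}

random_mutation_templates <- function(n, genome, genes = NULL) {
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      variant_type = character(0), variant_class = character(0),
                      gene = character(0), context = character(0),
                      population_af = numeric(0), stringsAsFactors = FALSE))
  }
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  pos <- floor(stats::runif(n, 1, genome$length[ci]))
  ref <- sample(c("C", "T"), n, replace = TRUE)   # pyrimidine convention
  alt <- mapply(function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), ref)
  ctx <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), ref,
                sample(c("A", "C", "G", "T"), n, replace = TRUE))
  cls <- sample(c("missense", "nonsense", "splice_site", "synonymous", "other"),
                n, replace = TRUE, prob = c(0.55, 0.1, 0.05, 0.2, 0.1))
  if (is.null(genes)) genes <- sprintf("GENE%05d", sample.int(18000, n, replace = TRUE))
  data.frame(chrom = genome$chrom[ci], pos = as.integer(pos), ref = ref,
             alt = alt, variant_type = "SNV", variant_class = cls,
             gene = genes, context = ctx, population_af = NA_real_,
             stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study design: 10 patients, 70% in the MEN1/DAXX
#' mutant subgroup, 2-5 primary regions plus lymph-node and liver
#' metastasis samples per patient, 200x depth, purities 0.3-0.9, a
#' planted metastasis-selected gene, and per-patient common/distinct
#' metastatic origin.
#'
#' @param n_patients,frac_mut Cohort size and mutant-subgroup fraction.
#' @param primary_regions,lymph_regions,liver_regions Integer ranges
#'   (min, max) of sampled regions per site.
#' @param depth Sequencing depth per locus.
#' @param purity_range Uniform range of tumor purity.
#' @param error_rate Per-read sequencing error probability.
#' @param fp_per_sample Poisson mean of sequencing-artifact false
#'   positives added per sample.
#' @param n_subclone_muts Poisson mean of mutations per subclone branch.
#' @param n_trunk_muts Poisson mean of truncal mutations. The defaults
#'   (120 truncal, 10 per subclone) put the per-sample burden near 150
#'   calls with roughly three quarters clonal and 40% of each
#'   patient's variants private, the burden structure reported for
#'   multiregion PanNET cohorts.
#' @param met_selected_gene Gene symbol planted as a metastasis-selected
#'   event in every patient.
#' @param met_primary_ccf CCF of the seeding subclone in the primary
#'   regions that carry it.
#' @param frac_common_origin Fraction of patients whose metastases are
#'   seeded by a subclone shared with a primary region.
#' @param nd_choices Planted dissemination sizes (cells at seeding),
#'   sampled per patient.
#' @param panel_mb Capture panel size in Mb.
#' @return Config list.
#' @export
cohort_config <- function(n_patients = 10, frac_mut = 0.7,
                          primary_regions = c(2, 5), lymph_regions = c(2, 4),
                          liver_regions = c(1, 2), depth = 200,
                          purity_range = c(0.3, 0.9), error_rate = 0.005,
                          fp_per_sample = 5, n_subclone_muts = 10,
                          n_trunk_muts = 120, met_selected_gene = "MSEL1",
                          met_primary_ccf = 0.3, frac_common_origin = 0.7,
                          nd_choices = c(1e4, 1e9), panel_mb = 30) {
  if (depth <= 0) stop("config error: depth must be positive")
  if (any(purity_range <= 0) || any(purity_range > 1))
    stop("config error: purity must be in (0, 1]")
  as.list(environment())
}

subtree_ccf <- function(parent, fractions) {
  # CCF of a mutation on the branch to clone c = sum of fractions over the
  # subtree rooted at c.
  n <- length(parent)
  ccf <- fractions
  for (i in rev(seq_len(n))) {
    if (parent[i] > 0) ccf[parent[i]] <- ccf[parent[i]] + ccf[i]
  }
  ccf
}

#' Expected variant allele frequency
#'
#' `VAF = purity * CCF * multiplicity / (purity * CN_t + 2 (1 - purity))`.
#'
#' @param ccf Cancer cell fraction.
#' @param purity Tumor purity.
#' @param cn_total Total copy number at the locus.
#' @param multiplicity Mutation copies per mutated cell.
#' @return Expected VAF.
#' @export
expected_vaf <- function(ccf, purity, cn_total = 2, multiplicity = 1) {
  purity * ccf * multiplicity / (purity * cn_total + 2 * (1 - purity))
}

#' Simulate a synthetic multiregion cohort
#'
#' Generates, per patient, a clone structure (trunk + region-private,
#' shared, seeding and metastasis-private subclones), samples per site,
#' binomial read counts at the configured depth from the expected-VAF
#' model, planted trunk MEN1/DAXX mutations in Mut patients, a planted
#' metastasis-selected gene, sequencing-artifact false positives, and
#' per-sample allele-specific segments on the toy genome (occasional LOH
#' segments exercise the copy-number-aware CCF path).
#'
#' @param config List from [cohort_config()].
#' @param seed Integer seed.
#' @return A cohort list with elements `sheet` (sample sheet data frame
#'   with pass-through `tnb` and `msi` columns), `variants` (named list of
#'   raw per-sample variant tables), `segments`, and `truth` (per patient:
#'   clone parents, mutation-to-clone map, per-sample clone fractions,
#'   per-sample true CCF matrix, metastatic origin, planted genes,
#'   dissemination size).
#' @export
simulate_multiregion_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  genome <- genome_arms("toy")
  sheet <- list(); variants <- list(); segments <- list(); truth <- list()
  n_mut_patients <- round(cfg$n_patients * cfg$frac_mut)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    group <- if (p <= n_mut_patients) "Mut" else "WT"
    met_origin <- if (stats::runif(1) < cfg$frac_common_origin) "common" else "distinct"
    pt <- simulate_patient(pid, group, met_origin, cfg, genome)
    sheet[[pid]] <- pt$sheet
    variants <- c(variants, pt$variants)
    segments <- c(segments, pt$segments)
    truth[[pid]] <- pt$truth
  }
  sheet <- do.call(rbind, sheet)
  rownames(sheet) <- NULL
  list(sheet = sheet, variants = variants, segments = segments,
       truth = truth, config = cfg)
}

simulate_patient <- function(pid, group, met_origin, cfg, genome) {
  rint <- function(rng) sample(seq(rng[1], rng[2]), 1)
  n_prim <- rint(cfg$primary_regions)
  n_lymph <- rint(cfg$lymph_regions)
  n_liver <- rint(cfg$liver_regions)
  sites <- c(rep("primary", n_prim), rep("lymph_node", n_lymph),
             rep("liver", n_liver))
  region <- c(seq_len(n_prim), seq_len(n_lymph), seq_len(n_liver))
  sample_ids <- paste0(pid, "_", c(paste0("PT", seq_len(n_prim)),
                                   paste0("LN", seq_len(n_lymph)),
                                   paste0("LI", seq_len(n_liver))))
  n_samp <- length(sample_ids)
  is_met <- sites != "primary"

  # Clone structure. Common origin models polyclonal seeding: two
  # seeding sub-lineages S1 and S2 (children of the trunk), each
  # dominating one primary region; E, a small sweep subclone of S1,
  # remains subclonal in S1's region and carries the metastasis-selected
  # gene. Each metastatic site receives samples seeded from BOTH
  # lineages (S1-seeded samples descend from E), so in the sample tree
  # the metastases of a site interleave with the seeding primary
  # regions — the tree signal the MRCA origin rule reads. Distinct
  # origin: one seeding clone D branches straight off the trunk and is
  # absent from every primary region, so its mutations are
  # metastasis-exclusive and the metastases form their own clade. Every
  # metastasis sample additionally carries its own private clone
  # (independent regional expansion), and each primary region a private
  # regional clone.
  n_met <- sum(is_met)
  if (met_origin == "common") {
    n_s <- 2L
    s_clone <- 1L + seq_len(n_s)          # S1, S2: children of trunk
    e_clone <- 2L + n_s                   # E: child of S1
    region_clone <- e_clone + seq_len(n_prim)
    met_clone <- e_clone + n_prim + seq_len(n_met)
    s_primary_regions <- sort(sample.int(n_prim, n_s))
    # alternate seeding source within each metastatic site so every
    # multi-sample site spans both seeding lineages
    met_sites <- sites[is_met]
    met_src <- integer(n_met)
    for (s in unique(met_sites)) {
      ix <- which(met_sites == s)
      met_src[ix] <- rep_len(seq_len(n_s), length(ix))
    }
    resident <- ifelse(met_src == 1L, e_clone, s_clone[met_src])
    region_parent <- rep(1L, n_prim)
    region_parent[s_primary_regions] <- s_clone   # local drift within S regions
    parent <- c(0L, rep(1L, n_s), s_clone[1], region_parent, resident)
    seeding_clone <- e_clone
  } else {
    n_s <- 0L
    seeding_clone <- 2L                   # D: child of trunk
    region_clone <- 2L + seq_len(n_prim)
    met_clone <- 2L + n_prim + seq_len(n_met)
    s_primary_regions <- integer(0)
    met_src <- rep(1L, n_met)
    resident <- rep(seeding_clone, n_met)
    parent <- c(0L, 1L, rep(1L, n_prim), rep(seeding_clone, n_met))
  }
  n_clones <- length(parent)

  n_mut <- stats::rpois(n_clones, cfg$n_subclone_muts)
  n_mut[1] <- stats::rpois(1, cfg$n_trunk_muts) + 1L
  if (met_origin == "common") {
    n_mut[s_clone] <- n_mut[s_clone] + 1L   # seeding lineages never empty
    n_mut[e_clone] <- stats::rpois(1, 3) + 1L  # the sweep clone carries few mutations
  }
  muts <- random_mutation_templates(sum(n_mut), genome)
  muts$clone <- rep(seq_len(n_clones), n_mut)
  # planted events: trunk MEN1 + DAXX for Mut patients; the metastasis-
  # selected gene rides the seeding clone of Mut patients.
  if (group == "Mut") {
    planted_trunk <- random_mutation_templates(2, genome,
                                               genes = c("MEN1", "DAXX"))
    planted_trunk$variant_class <- "missense"
    planted_trunk$clone <- 1L
    muts <- rbind(muts, planted_trunk)
    msel <- random_mutation_templates(1, genome, genes = cfg$met_selected_gene)
    msel$variant_class <- "missense"
    msel$clone <- seeding_clone
    muts <- rbind(msel, muts)
  }
  muts$mut_id <- paste0(pid, "_m", seq_len(nrow(muts)))

  # per-sample clone fractions
  frac <- matrix(0, n_samp, n_clones,
                 dimnames = list(sample_ids, paste0("clone", seq_len(n_clones))))
  met_idx <- 0L
  for (i in seq_len(n_samp)) {
    if (!is_met[i]) {
      r <- region[i]
      j <- match(r, s_primary_regions)
      if (!is.na(j)) {
        # region sampled from within seeding lineage j: S_j dominates
        # with minimal local drift; in S1's region E sweeps subclonally
        f_region <- stats::runif(1, 0.02, 0.08)
        if (j == 1L) {
          frac[i, e_clone] <- cfg$met_primary_ccf
          frac[i, s_clone[1]] <- 1 - cfg$met_primary_ccf - f_region
        } else {
          frac[i, s_clone[j]] <- 1 - f_region
        }
        frac[i, region_clone[r]] <- f_region
      } else {
        f_region <- stats::runif(1, 0.2, 0.4)
        frac[i, region_clone[r]] <- f_region
        frac[i, 1L] <- 1 - f_region
      }
    } else {
      met_idx <- met_idx + 1L
      f_m <- stats::runif(1, 0.3, 0.5)
      frac[i, met_clone[met_idx]] <- f_m
      frac[i, resident[met_idx]] <- 1 - f_m
    }
  }

  purity <- stats::runif(n_samp, cfg$purity_range[1], cfg$purity_range[2])
  # occasional LOH chromosome arm to exercise CN-aware CCF and scar code
  seg_list <- list(); var_list <- list()
  ccf_true <- matrix(0, nrow(muts), n_samp,
                     dimnames = list(muts$mut_id, sample_ids))
  for (i in seq_len(n_samp)) {
    seg <- data.frame(chrom = genome$chrom, start = 1L,
                      end = as.integer(genome$length),
                      major_cn = 1L, minor_cn = 1L, stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.25) {  # LOH of chr3
      seg$minor_cn[seg$chrom == "chr3"] <- 0L
    }
    ccf <- subtree_ccf(parent, frac[i, ])[muts$clone]
    ccf_true[, i] <- ccf
    carried <- ccf > 0
    v <- muts[carried, c("chrom", "pos", "ref", "alt", "variant_type",
                         "variant_class", "gene", "context", "population_af")]
    cn <- locus_copy_number(v, seg)
    evaf <- expected_vaf(ccf[carried], purity[i], cn$cn_total, 1)
    v$alt_count <- stats::rbinom(nrow(v), cfg$depth, pmin(evaf, 1))
    v$ref_count <- cfg$depth - v$alt_count
    v$strand_bias <- FALSE
    v$mut_id <- muts$mut_id[carried]
    # sequencing-error false positives
    n_fp <- stats::rpois(1, cfg$fp_per_sample)
    if (n_fp > 0) {
      fp <- random_mutation_templates(n_fp, genome)
      fp$alt_count <- pmax(stats::rbinom(n_fp, cfg$depth, cfg$error_rate), 1L)
      fp$ref_count <- cfg$depth - fp$alt_count
      fp$strand_bias <- FALSE
      fp$mut_id <- NA_character_
      v <- rbind(v, fp[, names(v)])
    }
    rownames(v) <- NULL
    var_list[[sample_ids[i]]] <- v
    seg_list[[sample_ids[i]]] <- seg
  }

  msi_base <- if (group == "Mut") 0.29 else 0.26
  tnb_base <- if (group == "Mut") 20 else 11
  sheet <- data.frame(
    sample_id = sample_ids, patient_id = pid, site = sites,
    region_index = region, purity = purity, group = group, ploidy = 2,
    tnb = stats::rpois(n_samp, tnb_base),
    msi = stats::rnorm(n_samp, msi_base, 0.01), stringsAsFactors = FALSE)

  list(sheet = sheet, variants = var_list, segments = seg_list,
       truth = list(parent = parent, mutations = muts,
                    clone_fractions = frac, ccf = ccf_true,
                    seeding_clone = seeding_clone, met_origin = met_origin,
                    met_sources = met_src,
                    planted_trunk_genes = if (group == "Mut") c("MEN1", "DAXX") else character(0),
                    met_selected_gene = cfg$met_selected_gene,
                    dissemination_Nd = sample(cfg$nd_choices, 1)))
}

#' Write a simulated cohort to disk
#'
#' Writes the minimal-MAF variant table, SEG segments, sample sheet and a
#' per-patient truth summary under `dir`.
#'
#' @param cohort List from [simulate_multiregion_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cohort$variants, file.path(dir, "variants.maf"))
  seg <- do.call(rbind, lapply(names(cohort$segments), function(s)
    cbind(sample = s, cohort$segments[[s]])))
  write_tsv(seg, file.path(dir, "segments.seg"))
  write_tsv(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  truth <- do.call(rbind, lapply(names(cohort$truth), function(p) {
    t <- cohort$truth[[p]]
    data.frame(patient_id = p, met_origin = t$met_origin,
               dissemination_Nd = t$dissemination_Nd,
               n_clones = length(t$parent), stringsAsFactors = FALSE)
  }))
  write_tsv(truth, file.path(dir, "truth_patients.tsv"))
  invisible(dir)
}

#' Growth model parameters
#'
#' @param u Mutation rate per cell division (expected exome-wide new
#'   mutations per daughter cell).
#' @param s Selection coefficient scaling down the death probability
#'   (0 = neutral; the model otherwise assumes a constant coefficient).
#' @param Nd Primary-tumor cell count at dissemination.
#' @param N_detect Final lesion size (default 1e9 cells).
#' @param early_threshold Cell-count boundary between early and late
#'   dissemination (1e8).
#' @param birth_prob Per-generation division probability of the
#'   Galton-Watson process (default 0.55; death probability
#'   `(1 - birth_prob) * (1 - s)`).
#' @param n_exact Population size up to which growth is simulated
#'   cell-by-cell; beyond it growth is deterministic-exponential with
#'   Poisson mutation bookkeeping along the seeding lineage.
#' @param detect_floor Minimum CCF reported (WES detectability stand-in).
#' @return Parameter list.
#' @export
growth_params <- function(u = 1, s = 0, Nd = 1e6, N_detect = 1e9,
                          early_threshold = 1e8, birth_prob = 0.55,
                          n_exact = 1000, detect_floor = 0.05) {
  if (u <= 0) stop("u must be > 0")
  if (Nd < 1 || Nd > N_detect) stop("Nd must lie in [1, N_detect]")
  death <- (1 - birth_prob) * (1 - s)
  list(u = u, s = s, Nd = Nd, N_detect = N_detect,
       early_threshold = early_threshold,
       birth_prob = 1 - death, n_exact = n_exact,
       detect_floor = detect_floor)
}

# One Galton-Watson generation: each cell divides with probability b into
# two daughters (else dies); each daughter acquires Poisson(u) new
# mutations, becoming a new genotype node when it does. State is a list
# of cells (node id per cell), node_parent, and mut_node (mutation ->
# node where it arose; mutation ids are creation order).
gw_generation <- function(state, u, b) {
  divide <- stats::runif(length(state$cells)) < b
  if (!any(divide)) { state$cells <- integer(0); return(state) }
  daughters <- rep(state$cells[divide], each = 2L)
  k <- stats::rpois(length(daughters), u)
  idx <- which(k > 0)
  if (length(idx) > 0) {
    new_nodes <- length(state$node_parent) + seq_along(idx)
    state$node_parent <- c(state$node_parent, daughters[idx])
    state$mut_node <- c(state$mut_node, rep(new_nodes, k[idx]))
    daughters[idx] <- new_nodes
  }
  state$cells <- daughters
  state$gens <- state$gens + 1L
  state
}

# Exact Galton-Watson phase: grow a single founder cell to `target`
# cells, conditioned on non-extinction (extinct runs are restarted).
gw_exact <- function(u, b, target) {
  repeat {
    state <- list(cells = 1L, node_parent = 0L, mut_node = integer(0),
                  gens = 0L)
    while (length(state$cells) >= 1 && length(state$cells) < target)
      state <- gw_generation(state, u, b)
    if (length(state$cells) >= target) break
  }
  state$n_mut <- length(state$mut_node)
  state
}

# Frequency of each mutation among `cells`, via subtree counts on the
# node tree (children always have larger indices than their parent).
gw_mut_freq <- function(phase) {
  counts <- tabulate(phase$cells, nbins = length(phase$node_parent))
  for (v in rev(seq_along(phase$node_parent))) {
    p <- phase$node_parent[v]
    if (p > 0) counts[p] <- counts[p] + counts[v]
  }
  if (phase$n_mut == 0) return(numeric(0))
  counts[phase$mut_node] / length(phase$cells)
}

# All mutation ids carried by one cell (walk up the node tree).
gw_cell_muts <- function(phase, cell_node) {
  anc <- logical(length(phase$node_parent))
  v <- cell_node
  while (v > 0) { anc[v] <- TRUE; v <- phase$node_parent[v] }
  which(anc[phase$mut_node])
}

#' Simulate primary-tumor growth with metastatic dissemination
#'
#' Discrete-generation Galton-Watson growth with neutral mutation
#' accumulation: the primary grows cell-by-cell to `n_exact` cells (above
#' which growth is treated as deterministic exponential expansion that
#' leaves detectable mutation frequencies unchanged), one cell sampled
#' when the primary reaches `Nd` cells seeds the metastasis, and the
#' seeding lineage accumulates Poisson mutations over the additional
#' divisions implied by `Nd`. The metastasis then grows independently by
#' the same model. Mutations with CCF below `detect_floor` are dropped
#' from the output, mimicking WES detectability.
#'
#' @param params List from [growth_params()].
#' @param seed Integer seed.
#' @return List with `primary` and `met` data frames (`mut_id`, `ccf`),
#'   and `truth` (the parameters).
#' @export
simulate_growth_with_dissemination <- function(params = growth_params(), seed = 1) {
  set.seed(seed)
  u <- params$u; b <- params$birth_prob
  growth_factor <- 2 * b
  if (growth_factor <= 1) stop("subcritical growth: birth_prob must exceed 0.5")

  if (params$Nd <= params$n_exact) {
    pre <- gw_exact(u, b, target = params$Nd)
    seed_cell <- sample(pre$cells, 1)
    seed_muts <- gw_cell_muts(pre, seed_cell)
    # continue the primary's exact phase from the dissemination snapshot
    primary <- gw_continue(pre, u, b, params$n_exact)
    extra_divisions <- 0L
  } else {
    primary <- gw_exact(u, b, target = params$n_exact)
    seed_cell <- sample(primary$cells, 1)
    anc_muts <- gw_cell_muts(primary, seed_cell)
    extra_divisions <- max(0L, ceiling(
      (log(params$Nd) - log(length(primary$cells))) / log(growth_factor)))
    n_extra <- stats::rpois(1, u * extra_divisions)
    seed_muts <- c(anc_muts, primary$n_mut + seq_len(n_extra))
  }
  met <- gw_exact(u, b, target = params$n_exact)
  prim_freq <- gw_mut_freq(primary)
  met_freq <- gw_mut_freq(met)

  # apply the detection floor before materializing id strings: only a
  # small fraction of mutations are detectable, and building ids for
  # all of them dominates the runtime otherwise
  floor_ <- params$detect_floor
  keep_p <- which(prim_freq >= floor_)
  keep_m <- which(met_freq >= floor_)
  # recycle0: zero-length inputs must give zero ids, not "m"
  prim_df <- data.frame(mut_id = paste0("m", keep_p, recycle0 = TRUE),
                        ccf = prim_freq[keep_p], stringsAsFactors = FALSE)
  met_df <- data.frame(
    mut_id = c(paste0("m", seed_muts, recycle0 = TRUE),
               paste0("met_m", keep_m, recycle0 = TRUE)),
    ccf = c(rep(1, length(seed_muts)), met_freq[keep_m]),
    stringsAsFactors = FALSE)
  list(primary = prim_df, met = met_df, truth = params)
}

# Continue an exact phase (after a dissemination snapshot) to `target`,
# conditioned on non-extinction of the continuation.
gw_continue <- function(phase, u, b, target) {
  repeat {
    state <- phase
    while (length(state$cells) >= 1 && length(state$cells) < target)
      state <- gw_generation(state, u, b)
    if (length(state$cells) >= target) {
      state$n_mut <- length(state$mut_node)
      return(state)
    }
  }
}
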