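# Per-patient sample phylogenies from binary mutation matrices:
# neighbor joining on Hamming distances, Fitch parsimony scoring, maximum
# parsimony search (exhaustive for small trees, NNI hill-climbing
# otherwise), column bootstrap supports, and the common/distinct
# metastatic-origin call. The germline all-zero profile roots every tree.

GERMLINE <- "germline"

#' Binary mutation matrix for one patient
#'
#' Rows are the patient's samples plus an all-zero germline outgroup row;
#' columns are unique variants (keyed by chrom, pos, ref, alt); entries
#' record post-filter presence (1) or wild-type status (0).
#'
#' @param variants_by_sample Named list of retained variant data frames
#'   (>= 2 samples).
#' @return Integer 0/1 matrix.
#' @export
binary_matrix <- function(variants_by_sample) {
  if (length(variants_by_sample) < 2) stop("need >= 2 samples")
  if (any(duplicated(names(variants_by_sample)))) stop("duplicate sample ids")
  keys <- lapply(variants_by_sample, function(v) unique(variant_key(v)))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  m <- t(vapply(keys, function(k) as.integer(all_keys %in% k),
                integer(length(all_keys))))
  m <- rbind(m, 0L)
  rownames(m) <- c(names(variants_by_sample), GERMLINE)
  colnames(m) <- all_keys
  m[, colSums(m) > 0, drop = FALSE]
}

hamming_dist <- function(mat) stats::dist(mat, method = "manhattan")

#' Neighbor-joining tree from a binary mutation matrix
#'
#' Pairwise unnormalized Hamming distances, Saitou-Nei neighbor joining,
#' negative branch lengths clamped to zero, rooted on the germline leaf.
#'
#' @param mat Binary matrix from [binary_matrix()] (>= 3 rows).
#' @return A rooted [ape::phylo] tree.
#' @export
nj_tree <- function(mat) {
  if (nrow(mat) < 3) stop("neighbor joining needs >= 3 rows")
  if (any(duplicated(rownames(mat)))) stop("duplicate sample ids")
  tr <- ape::nj(hamming_dist(mat))
  tr$edge.length[tr$edge.length < 0] <- 0
  root_on_germline(tr)
}

root_on_germline <- function(tr) {
  if (GERMLINE %in% tr$tip.label)
    tr <- ape::root(tr, outgroup = GERMLINE, resolve.root = TRUE)
  tr
}

#' Fitch parsimony score of a tree on a binary matrix
#'
#' Sum over variant columns of the Fitch small-parsimony state-change
#' count on the given topology (multifurcations handled by the set
#' intersection/union generalization).
#'
#' @param tree An [ape::phylo] whose tip labels equal the matrix rows.
#' @param mat Binary matrix.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, mat) {
  if (!setequal(tree$tip.label, rownames(mat)))
    stop("tree leaves do not match matrix rows")
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  n_col <- ncol(mat)
  # state sets as bitmasks: state 0 -> 1, state 1 -> 2
  states <- matrix(0L, n_node, n_col)
  states[seq_len(n_tip), ] <- mat[tr$tip.label, , drop = FALSE] + 1L
  score <- integer(n_col)
  for (node in unique(tr$edge[, 1])) {   # postorder of internal nodes
    children <- tr$edge[tr$edge[, 1] == node, 2]
    acc <- states[children[1], ]
    for (ch in children[-1]) {
      inter <- bitwAnd(acc, states[ch, ])
      empty <- inter == 0L
      score <- score + empty
      acc <- ifelse(empty, bitwOr(acc, states[ch, ]), inter)
    }
    states[node, ] <- acc
  }
  sum(score)
}

#' Maximum parsimony tree search
#'
#' For matrices with at most `exhaustive_max` leaves, scores every
#' unrooted topology and returns the first minimum under the deterministic
#' enumeration order. Larger matrices are searched by nearest-neighbor-
#' interchange hill climbing from the neighbor-joining tree until no move
#' improves the score.
#'
#' @param mat Binary matrix from [binary_matrix()].
#' @param exhaustive_max Leaf-count cutoff for exhaustive enumeration
#'   (default 8, i.e. up to 10,395 topologies).
#' @return A rooted [ape::phylo] tree with attribute `"pscore"`.
#' @export
mp_search <- function(mat, exhaustive_max = 8) {
  if (nrow(mat) < 3) stop("need >= 3 rows")
  n <- nrow(mat)
  if (n <= exhaustive_max) {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(mat))
    scores <- vapply(trees, parsimony_score, integer(1), mat = mat)
    best <- trees[[which.min(scores)]]
    best$edge.length <- rep(1, nrow(best$edge))
    best <- root_on_germline(best)
    attr(best, "pscore") <- min(scores)
    return(best)
  }
  tr <- ape::unroot(nj_tree(mat))
  cur <- parsimony_score(tr, mat)
  repeat {
    nbrs <- phangorn::nni(tr)
    scores <- vapply(nbrs, parsimony_score, integer(1), mat = mat)
    if (min(scores) >= cur) break
    tr <- nbrs[[which.min(scores)]]
    cur <- min(scores)
  }
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr <- root_on_germline(tr)
  attr(tr, "pscore") <- cur
  tr
}

#' Bootstrap supports for a sample tree
#'
#' Resamples variant columns with replacement B times, rebuilds the tree
#' with the chosen builder, and reports for each internal edge of the
#' full-data tree the percentage of replicates containing the same
#' bipartition. Supports are stored in `node.label`.
#'
#' @param mat Binary matrix (>= 4 rows for informative supports).
#' @param builder `"nj"` or `"mp"`.
#' @param B Number of replicates (default 100).
#' @param seed Integer seed.
#' @return The full-data tree with bootstrap percentages as node labels.
#' @export
bootstrap_support <- function(mat, builder = c("nj", "mp"), B = 100, seed = 1) {
  builder <- match.arg(builder)
  if (B < 1) stop("B must be >= 1")
  build <- if (builder == "nj") nj_tree else mp_search
  main <- build(mat)
  set.seed(seed)
  reps <- lapply(seq_len(B), function(b) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    build(mat[, cols, drop = FALSE])
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / B, 1)
  main
}

#' Classify metastatic sites as common or distinct origin
#'
#' For each metastatic site, takes the most recent common ancestor of that
#' site's leaves in the germline-rooted tree (for a single leaf, its
#' parent node) and calls the origin `common` when the ancestor's leaf
#' descendants include at least one primary-tumor sample, `distinct`
#' otherwise.
#'
#' @param tree Rooted [ape::phylo] with germline leaf.
#' @param sample_sites Named character vector mapping each non-germline
#'   tip label to `primary`, `lymph_node` or `liver`.
#' @return Named character vector over the metastatic sites present.
#' @export
classify_met_origin <- function(tree, sample_sites) {
  tips <- setdiff(tree$tip.label, GERMLINE)
  if (!all(tips %in% names(sample_sites)))
    stop("sample_sites missing for: ",
         paste(setdiff(tips, names(sample_sites)), collapse = ", "))
  sites <- sample_sites[tips]
  primary_tips <- tips[sites == "primary"]
  if (length(primary_tips) == 0) stop("no primary sample in tree")
  met_sites <- intersect(c("lymph_node", "liver"), unique(sites))
  if (length(met_sites) == 0) stop("no metastatic sample in tree")
  out <- character(0)
  for (ms in met_sites) {
    ms_tips <- tips[sites == ms]
    idx <- match(ms_tips, tree$tip.label)
    node <- if (length(idx) == 1) tree$edge[tree$edge[, 2] == idx, 1]
            else ape::getMRCA(tree, ms_tips)
    desc <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    out[ms] <- if (any(desc %in% primary_tips)) "common" else "distinct"
  }
  out
}
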