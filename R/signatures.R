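# Mutational signature analysis: 96-channel trinucleotide catalogs,
# de novo extraction by multiplicative-update NMF with consensus
# clustering and cophenetic rank selection, cosine matching against a
# reference signature set, and non-negative least-squares exposures.

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The fixed 96-channel order
#'
#' Channels are grouped by pyrimidine substitution (C>A, C>G, C>T, T>A,
#' T>C, T>G) and within each substitution ordered by 5' then 3' flanking
#' base (A, C, G, T) — the conventional catalog ordering.
#'
#' @return Character vector of 96 channel names like `"A[C>A]A"`.
#' @export
channel_names_96 <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s)
    unlist(lapply(BASES, function(p) paste0(p, "[", s, "]", BASES)))))
}

revcomp <- function(x) chartr("ACGT", "TGCA",
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), ""))

#' Build the 96-channel mutation catalog of one sample
#'
#' SNVs with a trinucleotide context are tallied into the 96 channels;
#' purine-centered contexts are reverse-complemented to the pyrimidine
#' convention. Indels and context-free SNVs are excluded (their count is
#' reported in the `n_excluded` attribute).
#'
#' @param variants Data frame of variant records.
#' @return Named integer vector of length 96.
#' @export
catalog_96 <- function(variants) {
  ch <- channel_names_96()
  counts <- stats::setNames(integer(96), ch)
  v <- variants[variants$variant_type == "SNV" & !is.na(variants$context), ,
                drop = FALSE]
  n_excluded <- nrow(variants) - nrow(v)
  if (nrow(v) > 0) {
    ref <- v$ref; alt <- v$alt; ctx <- toupper(v$context)
    pur <- ref %in% c("A", "G")
    ref[pur] <- chartr("ACGT", "TGCA", v$ref[pur])
    alt[pur] <- chartr("ACGT", "TGCA", v$alt[pur])
    ctx[pur] <- revcomp(ctx[pur])
    if (any(substr(ctx, 2, 2) != ref))
      stop("context middle base does not match ref allele")
    name <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
    bad <- !name %in% ch
    if (any(bad)) stop("invalid substitution channel: ", name[bad][1])
    tab <- table(name)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  attr(counts, "n_excluded") <- n_excluded
  counts
}

#' Catalog matrix for a set of samples
#' @param variants_by_sample Named list of variant data frames.
#' @return 96 x n_samples integer matrix.
#' @export
catalog_matrix <- function(variants_by_sample) {
  m <- vapply(variants_by_sample, function(v) as.integer(catalog_96(v)),
              integer(96))
  rownames(m) <- channel_names_96()
  m
}

# One multiplicative-update NMF run (Frobenius objective).
nmf_run <- function(V, k, max_iter = 2000, tol = 1e-6) {
  p <- nrow(V); n <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(p * k, 0.1, 1), p, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps))
        break
      err_prev <- err
    }
  }
  err <- sqrt(sum((V - W %*% H)^2))
  # scale signatures to the simplex; move the scale into exposures
  cs <- pmax(colSums(W), eps)
  list(W = sweep(W, 2, cs, "/"), H = H * cs, err = err)
}

#' De novo signature extraction with cophenetic rank selection
#'
#' For each candidate rank k, runs `n_restarts` NMF factorizations
#' (multiplicative updates, Frobenius objective) of the 96 x samples
#' catalog matrix. Sample connectivity matrices (samples co-assigned to
#' the same dominant signature) are averaged into a consensus matrix whose
#' cophenetic correlation coefficient measures clustering stability. The
#' selected k maximizes the cophenetic coefficient (ties broken toward
#' smaller k); signatures from the best-error restart at that k are
#' returned column-normalized.
#'
#' @param catalogs 96 x n_samples matrix ([catalog_matrix()]).
#' @param k_range Integer vector of candidate ranks (within
#'   2..n_samples-1).
#' @param n_restarts NMF restarts per rank (default 30).
#' @param seed Integer seed; the run is deterministic given it.
#' @param max_iter,tol Update-loop controls.
#' @return List with `k`, `signatures` (96 x k, columns on the simplex),
#'   `exposures` (k x n, columns renormalized to 1), `cophenetic_by_k`,
#'   `recon_error_by_k`.
#' @export
nmf_denovo <- function(catalogs, k_range = 2:5, n_restarts = 30, seed = 1,
                       max_iter = 2000, tol = 1e-6) {
  V <- as.matrix(catalogs)
  if (ncol(V) < 2) stop("need >= 2 samples")
  if (any(colSums(V) == 0)) stop("all-zero catalog column")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > ncol(V) - 1))
    stop("k_range must lie within [2, n_samples - 1]")
  coph <- stats::setNames(numeric(length(k_range)), k_range)
  best <- stats::setNames(vector("list", length(k_range)), k_range)
  err_k <- stats::setNames(numeric(length(k_range)), k_range)
  n <- ncol(V)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    consensus <- matrix(0, n, n)
    best_run <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed * 10000L + k * 100L + r)
      run <- nmf_run(V, k, max_iter, tol)
      assign <- apply(run$H, 2, which.max)
      consensus <- consensus + outer(assign, assign, "==")
      if (is.null(best_run) || run$err < best_run$err) best_run <- run
    }
    consensus <- consensus / n_restarts
    coph[ki] <- cophenetic_coefficient(consensus)
    best[[ki]] <- best_run
    err_k[ki] <- best_run$err
  }
  k_sel <- k_range[which.max(coph)]   # which.max takes the first (smallest k) tie
  run <- best[[as.character(k_sel)]]
  expo <- sweep(run$H, 2, pmax(colSums(run$H), 1e-12), "/")
  rownames(run$W) <- rownames(V)
  colnames(run$W) <- paste0("denovo_", seq_len(k_sel))
  rownames(expo) <- colnames(run$W)
  colnames(expo) <- colnames(V)
  list(k = k_sel, signatures = run$W, exposures = expo,
       cophenetic_by_k = coph, recon_error_by_k = err_k)
}

cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (all(d == d[1])) return(1)  # degenerate: perfectly stable clustering
  hc <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(hc))
}

#' Cosine similarity match against a reference signature set
#'
#' @param signature Numeric 96-vector.
#' @param reference_set 96 x m matrix with signature ids as column names.
#' @return List with `best_id`, `similarity`, and the full `similarities`
#'   row over the reference set.
#' @export
match_cosine <- function(signature, reference_set) {
  ref <- as.matrix(reference_set)
  stopifnot(length(signature) == nrow(ref))
  sims <- apply(ref, 2, cosine_similarity, b = signature)
  best <- which.max(sims)
  list(best_id = colnames(ref)[best], similarity = unname(sims[best]),
       similarities = sims)
}

#' Cosine similarity of two non-negative vectors
#' @param a,b Numeric vectors of equal length.
#' @return `dot(a, b) / (|a| |b|)`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Fit signature exposures by non-negative least squares
#'
#' Regresses a sample's normalized catalog on a fixed signature matrix
#' under non-negativity, then renormalizes exposures to sum to 1.
#'
#' @param catalog Numeric 96-vector of counts.
#' @param signatures 96 x k signature matrix.
#' @return Named exposure vector (non-negative, sums to 1).
#' @export
fit_exposures <- function(catalog, signatures) {
  W <- as.matrix(signatures)
  v <- as.numeric(catalog)
  if (sum(v) > 0) v <- v / sum(v)
  fit <- pracma::lsqnonneg(W, v)
  x <- pmax(fit$x, 0)
  if (sum(x) > 0) x <- x / sum(x)
  stats::setNames(as.numeric(x), colnames(W))
}

#' Load the packaged synthetic reference signature set
#'
#' A small set of synthetic reference signatures shipped with the package
#' (constructed shapes: spontaneous-deamination-like C>T, C>A-heavy,
#' T>C-heavy, flat, and APOBEC-like C>G/C>T at TpC). These are synthetic
#' stand-ins for an external reference catalog and carry no claim of
#' equivalence to any published signature.
#'
#' @return 96 x 5 matrix, columns on the simplex.
#' @export
synthetic_reference_signatures <- function() {
  path <- system.file("extdata", "synthetic_reference_signatures.tsv",
                      package = "mrsevo")
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
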