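# Evaluation metrics for clusterings against external cell labels, plus the
# grid-entropy criterion used to choose between 2D embeddings. Unassigned
# cells (NA labels) are excluded from purity and AMI, which are computed on
# the robust clusters only. The Rand index is deliberately not provided: it
# penalizes splitting one true cell type into several clusters, which is the
# expected (and desirable) outcome when a novel subtype is resolved.

drop_unassigned <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

#' Per-cluster purity against external labels
#'
#' Purity of cluster i is the fraction of its cells carrying the cluster's
#' dominant external label (argmax ties broken by lexicographic label
#' order). Cells with an NA cluster label (unassigned) are excluded.
#'
#' @param clusters per-cell cluster labels; NA means unassigned.
#' @param truth per-cell external labels (e.g. sorted cell types).
#' @return list with `per_cluster` (named numeric), `median` and `mean`
#'   purity across clusters.
#' @export
cluster_purity <- function(clusters, truth) {
  if (length(clusters) != length(truth))
    stop("`clusters` and `truth` must have equal length")
  p <- drop_unassigned(clusters, truth)
  if (length(p$a) == 0L)
    stop("no assigned cells overlap the external labels")
  per <- vapply(split(as.character(p$b), as.character(p$a)), function(lab) {
    tab <- table(lab)
    dom <- sort(names(tab)[tab == max(tab)])[1]  # lexicographic tie-break
    unname(tab[dom]) / length(lab)
  }, numeric(1))
  list(per_cluster = per,
       median = stats::median(per),
       mean = mean(per))
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model:
# for each (row sum a_i, column sum b_j) pair, sum over the feasible joint
# counts n_ij weighted by the hypergeometric probability of observing them.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      emi <- emi + sum(term * stats::dhyper(nij, ai, n - ai, bj))
    }
  }
  emi
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement under the permutation
#' model and normalized by the larger of the two label entropies:
#' `AMI = (MI - E[MI]) / (max(H(a), H(b)) - E[MI])`. The chance correction
#' removes the spurious inflation of MI that occurs when one labeling has
#' many small clusters. Cells unassigned (NA) in either labeling are
#' excluded pairwise.
#'
#' @param a,b per-cell labels of equal length.
#' @return a single number; 1 for labelings identical up to renaming, near 0
#'   for independent labelings. Degenerate single-label inputs return 0 with
#'   a warning.
#' @export
adjusted_mutual_information <- function(a, b) {
  if (length(a) != length(b))
    stop("labelings must have equal length")
  p <- drop_unassigned(a, b)
  n <- length(p$a)
  if (n == 0L) stop("no cells assigned in both labelings")
  tab <- table(as.character(p$a), as.character(p$b))
  ai <- rowSums(tab)
  bj <- colSums(tab)
  if (length(ai) < 2L || length(bj) < 2L) {
    warning("a labeling has a single label; AMI undefined, returning 0")
    return(0)
  }
  ha <- entropy_nats(ai)
  hb <- entropy_nats(bj)
  nij <- tab[tab > 0]
  outer_ab <- outer(ai, bj)[tab > 0]
  mi <- sum(nij / n * log(n * nij / outer_ab))
  emi <- expected_mi(as.integer(ai), as.integer(bj), n)
  denom <- max(ha, hb) - emi
  if (abs(denom) < .Machine$double.eps * 64) return(0)
  (mi - emi) / denom
}

#' Proportion of cells assigned to robust clusters
#'
#' @param clusters per-cell cluster labels; NA means unassigned.
#' @return fraction of cells with a non-NA label.
#' @export
proportion_robustly_clustered <- function(clusters) {
  if (length(clusters) == 0L) return(0)
  mean(!is.na(clusters))
}

#' Shannon entropy of a 2D embedding on a regular grid
#'
#' Bins each axis of a cells-by-2 embedding into `bins_per_axis` equal-width
#' intervals spanning the observed range, forms the 2D histogram, and
#' returns the entropy (in nats) of the normalized bin counts. High entropy
#' means cells spread over many bins — an embedding that captures more
#' structure than one collapsing cells into few spots. A zero-range axis
#' collapses to a single bin.
#'
#' @param embedding cells-by-2 numeric matrix.
#' @param bins_per_axis number of bins per axis (default 20, i.e. a 20x20
#'   grid with entropy capped at `log(400)`).
#' @return entropy in nats.
#' @export
embedding_grid_entropy <- function(embedding, bins_per_axis = 20L) {
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2L, nrow(embedding) >= 1L, bins_per_axis >= 1L)
  bin_axis <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    breaks <- seq(r[1], r[2], length.out = bins_per_axis + 1L)
    as.integer(cut(x, breaks = breaks, include.lowest = TRUE))
  }
  ix <- bin_axis(embedding[, 1])
  iy <- bin_axis(embedding[, 2])
  entropy_nats(table(ix + (iy - 1L) * bins_per_axis))
}

#' Choose between PCA and t-SNE by 2D grid entropy
#'
#' Computes a 2-component PCA and a 2D t-SNE of the log1p-transformed 500
#' most variable genes, scores each by [embedding_grid_entropy()], and picks
#' the embedding with the higher information content (ties go to PCA, the
#' cheaper and deterministic option).
#'
#' @param expr genes-by-cells expression matrix.
#' @param seed integer seed for t-SNE.
#' @param n_var_genes number of most-variable genes used (capped at the
#'   number available).
#' @param bins_per_axis grid resolution for the entropy.
#' @return list with `choice` ("pca" or "tsne"), `entropy` (named numeric of
#'   both entropies) and `embeddings` (the two cells-by-2 matrices).
#' @export
choose_embedding <- function(expr, seed, n_var_genes = 500L,
                             bins_per_axis = 20L) {
  expr <- validate_expression(expr)
  x <- t(log1p(select_variable_genes(expr, min(n_var_genes, nrow(expr)))))
  pca2 <- stats::prcomp(x, rank. = 2L)$x
  tsne2 <- run_tsne(x, dims = 2L, seed = seed)
  ent <- c(pca = embedding_grid_entropy(pca2, bins_per_axis),
           tsne = embedding_grid_entropy(tsne2, bins_per_axis))
  list(choice = if (ent["tsne"] > ent["pca"]) "tsne" else "pca",
       entropy = ent,
       embeddings = list(pca = pca2, tsne = tsne2))
}
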