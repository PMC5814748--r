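# Robust consensus clustering: cluster many reduced-dimension views of the
# data with PAM over a range of K, record how often each pair of cells lands
# in the same cluster, cut the consensus dendrogram into high-affinity
# blocks, and merge blocks that show no differential expression. Cells that
# never reach a stable block stay unassigned — robustness over coverage.

# t-SNE wrapper: perplexity shrinks automatically for small datasets
# (Rtsne requires 3 * perplexity < n - 1).
run_tsne <- function(x, dims, seed, perplexity = 30) {
  perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
  if (perplexity < 1)
    stop("too few cells for t-SNE")
  out <- withr::with_seed(seed,
    Rtsne::Rtsne(x, dims = dims, perplexity = perplexity,
                 check_duplicates = FALSE, pca = TRUE, verbose = FALSE))
  emb <- out$Y
  rownames(emb) <- rownames(x)
  emb
}

#' Select the most variable genes
#'
#' Ranks genes by the variance of their log1p-transformed values across
#' cells and returns the top `n`, keeping the original row order among the
#' selected. Restricting analyses to highly variable genes lets biological
#' variation dominate technical noise.
#'
#' @param expr genes-by-cells expression matrix.
#' @param n number of genes to keep (`n <= nrow(expr)`).
#' @return the subset expression matrix (values untransformed).
#' @export
select_variable_genes <- function(expr, n) {
  expr <- validate_expression(expr)
  if (n > nrow(expr))
    stop("`n` exceeds the number of genes")
  v <- apply(log1p(expr), 1L, stats::var)
  sel <- sort(order(v, decreasing = TRUE)[seq_len(n)])
  expr[sel, , drop = FALSE]
}

#' Build the reduced-dimension views for consensus clustering
#'
#' Produces the view menu clustered by [pam_sweep()]: either PCA of the
#' log1p 500 most variable genes with 5/15/50 components, or seeded t-SNE of
#' the same genes with 2/3 dimensions, plus the raw log1p profiles of the
#' top 100/500/1000 most variable genes. Counts are capped at what the data
#' supports: a PCA view needing more components than cells is dropped with
#' a warning, and top-gene counts are capped at the number of genes
#' (duplicate views arising from the cap are collapsed).
#'
#' @param expr genes-by-cells expression matrix.
#' @param embedding "pca" or "tsne" (chosen upstream, e.g. by
#'   [choose_embedding()]).
#' @param seed integer seed for the t-SNE views.
#' @param n_var_genes genes used for the embedding views (default 500).
#' @param pca_dims,tsne_dims,top_counts the view menu.
#' @return named list of cells-by-d numeric matrices.
#' @export
make_views <- function(expr, embedding = c("pca", "tsne"), seed,
                       n_var_genes = 500L,
                       pca_dims = c(5L, 15L, 50L),
                       tsne_dims = c(2L, 3L),
                       top_counts = c(100L, 500L, 1000L)) {
  expr <- validate_expression(expr)
  embedding <- match.arg(embedding)
  n_cells <- ncol(expr)
  x <- t(log1p(select_variable_genes(expr, min(n_var_genes, nrow(expr)))))
  views <- list()
  if (embedding == "pca") {
    for (d in pca_dims) {
      if (d >= n_cells || d > ncol(x)) {
        warning(sprintf("dropping PCA view with %d components (%d cells)",
                        d, n_cells))
        next
      }
      views[[sprintf("pca%d", d)]] <- stats::prcomp(x, rank. = d)$x
    }
  } else {
    for (d in tsne_dims) {
      views[[sprintf("tsne%d", d)]] <- run_tsne(x, dims = d, seed = seed + d)
    }
  }
  used <- integer()
  for (k in top_counts) {
    kk <- min(k, nrow(expr))
    if (kk %in% used) next  # cap collapsed two top-gene views into one
    used <- c(used, kk)
    views[[sprintf("top%d", kk)]] <-
      t(log1p(select_variable_genes(expr, kk)))
  }
  views
}

#' PAM clustering across views and cluster counts
#'
#' Runs partitioning-around-medoids on every (view, K) combination for K
#' from `k_min` to `k_max`. PAM's BUILD initialization is deterministic, so
#' the sweep is reproducible without explicit seeding.
#'
#' @param views list of cells-by-d matrices from [make_views()].
#' @param k_min,k_max cluster-count range (defaults 5 and 10).
#' @return list of integer label vectors, one per (view, K) pair.
#' @export
pam_sweep <- function(views, k_min = 5L, k_max = 10L) {
  stopifnot(length(views) >= 1L, k_min >= 2L, k_max >= k_min)
  n_cells <- nrow(views[[1]])
  if (n_cells <= k_max)
    stop("need more cells than the largest K")
  labelings <- list()
  for (vn in names(views)) {
    for (k in k_min:k_max) {
      cl <- cluster::pam(views[[vn]], k = k, cluster.only = TRUE,
                         pamonce = 5)
      labelings[[sprintf("%s_k%d", vn, k)]] <- as.integer(cl)
    }
  }
  labelings
}

#' Co-clustering matrix
#'
#' Entry (i, j) is the fraction of labelings in which cells i and j share a
#' cluster; the diagonal is 1.
#'
#' @param labelings list of equal-length integer label vectors.
#' @param cell_ids optional cell identifiers for the dimnames.
#' @return symmetric cells-by-cells matrix with entries in \[0, 1\].
#' @export
cocluster_matrix <- function(labelings, cell_ids = NULL) {
  stopifnot(length(labelings) >= 1L)
  n <- length(labelings[[1]])
  cc <- matrix(0, n, n)
  for (l in labelings) {
    if (length(l) != n) stop("labelings must have equal length")
    # indicator crossproduct: cells sharing a label in this run
    ind <- outer(l, l, "==")
    cc <- cc + ind
  }
  cc <- cc / length(labelings)
  if (!is.null(cell_ids)) dimnames(cc) <- list(cell_ids, cell_ids)
  cc
}

# Leaves under each node of an hclust merge tree.
hclust_members <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    members[[i]] <- c(
      if (m[1] < 0) -m[1] else members[[m[1]]],
      if (m[2] < 0) -m[2] else members[[m[2]]])
  }
  members
}

#' Consensus clusters from a co-clustering matrix
#'
#' Builds an average-linkage dendrogram on the dissimilarity
#' `1 - cocluster` and traverses it from the root downward, emitting a
#' cluster at the highest node whose block satisfies both criteria: mean
#' pairwise co-clustering at least `self_similarity` and at least
#' `min_size` cells. Descendants of an emitted block are not revisited;
#' cells in no emitted block are unassigned (NA).
#'
#' @param cocluster symmetric cells-by-cells co-clustering matrix.
#' @param self_similarity minimum mean within-block co-clustering
#'   (default 0.6).
#' @param min_size minimum block size (default 20 cells).
#' @return integer label vector (NA = unassigned), named by the matrix's
#'   dimnames when present.
#' @export
consensus_clusters <- function(cocluster, self_similarity = 0.6,
                               min_size = 20L) {
  cocluster <- as.matrix(cocluster)
  n <- nrow(cocluster)
  stopifnot(n == ncol(cocluster))
  if (max(abs(cocluster - t(cocluster))) > 1e-8)
    stop("co-clustering matrix must be symmetric")
  if (any(cocluster < -1e-12) || any(cocluster > 1 + 1e-12))
    stop("co-clustering entries must lie in [0, 1]")
  labels <- rep(NA_integer_, n)
  names(labels) <- rownames(cocluster)
  block_ok <- function(cells) {
    if (length(cells) < min_size) return(FALSE)
    m <- cocluster[cells, cells]
    mean(m[upper.tri(m)]) >= self_similarity
  }
  if (n < 2L) {
    if (block_ok(seq_len(n))) labels[] <- 1L
    return(labels)
  }
  hc <- stats::hclust(stats::as.dist(1 - cocluster), method = "average")
  members <- hclust_members(hc)
  next_label <- 1L
  emit <- function(node) {
    cells <- if (node < 0) -node else members[[node]]
    if (block_ok(cells)) {
      labels[cells] <<- next_label
      next_label <<- next_label + 1L
    } else if (node > 0) {
      emit(hc$merge[node, 1])
      emit(hc$merge[node, 2])
    }
  }
  emit(nrow(hc$merge))
  labels
}

# Medoid cell of each cluster in the metric of the supplied profile matrix
# (genes x cells): the member minimizing total distance to its cluster-mates.
cluster_medoids <- function(profiles, labels) {
  cls <- sort(unique(labels[!is.na(labels)]))
  idx <- vapply(cls, function(cl) {
    cells <- which(labels == cl)
    if (length(cells) == 1L) return(cells)
    d <- as.matrix(stats::dist(t(profiles[, cells, drop = FALSE])))
    cells[which.min(rowSums(d))]
  }, integer(1))
  names(idx) <- as.character(cls)
  idx
}

#' Merge clusters with no differential expression
#'
#' Hierarchically clusters the cluster medoids (average linkage, Euclidean
#' distance on log1p profiles of the 500 most variable genes), then tests
#' each pair of clusters adjacent in that hierarchy with a per-gene
#' two-sided Wilcoxon rank-sum test and Benjamini-Hochberg correction over
#' all genes. A pair is merged when fewer than `de_proportion_threshold` of
#' genes are differentially expressed at adjusted p < `adj_p`; the process
#' repeats until no pair merges. Singleton clusters are skipped from
#' testing (warning) and never merged; unassigned cells stay unassigned.
#'
#' @param expr genes-by-cells expression matrix (same cells as `labels`).
#' @param labels integer cluster labels with NA for unassigned cells.
#' @param de_proportion_threshold merge when the DE gene fraction is below
#'   this (default 0.1).
#' @param adj_p BH-adjusted significance cutoff per gene (default 0.05).
#' @param n_var_genes genes used for the medoid dendrogram (default 500).
#' @return relabeled integer vector (labels renumbered 1..k).
#' @export
merge_similar_clusters <- function(expr, labels,
                                   de_proportion_threshold = 0.1,
                                   adj_p = 0.05, n_var_genes = 500L) {
  expr <- validate_expression(expr)
  if (length(labels) != ncol(expr))
    stop("one label per cell required")
  logx <- log1p(expr)
  vexpr <- log1p(select_variable_genes(expr, min(n_var_genes, nrow(expr))))
  de_fraction <- function(c1, c2) {
    i1 <- which(labels == c1); i2 <- which(labels == c2)
    p <- apply(logx, 1L, function(g)
      suppressWarnings(
        stats::wilcox.test(g[i1], g[i2], exact = FALSE)$p.value))
    p[is.na(p)] <- 1  # constant genes carry no evidence
    mean(stats::p.adjust(p, method = "BH") < adj_p)
  }
  repeat {
    cls <- sort(unique(labels[!is.na(labels)]))
    if (length(cls) < 2L) break
    sizes <- table(factor(labels, levels = cls))
    if (any(sizes == 1L))
      warning("singleton cluster(s) skipped from merge testing")
    med <- cluster_medoids(vexpr, labels)
    hc <- stats::hclust(stats::dist(t(vexpr[, med, drop = FALSE])),
                        method = "average")
    # candidate pairs: clusters joined directly (leaf-leaf merges), nearest
    # first
    leafpairs <- which(hc$merge[, 1] < 0 & hc$merge[, 2] < 0)
    leafpairs <- leafpairs[order(hc$height[leafpairs])]
    merged <- FALSE
    for (node in leafpairs) {
      c1 <- cls[-hc$merge[node, 1]]
      c2 <- cls[-hc$merge[node, 2]]
      if (sizes[as.character(c1)] == 1L || sizes[as.character(c2)] == 1L)
        next
      if (de_fraction(c1, c2) < de_proportion_threshold) {
        labels[labels == c2] <- c1
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # renumber to consecutive labels, preserving order of first appearance
  cls <- sort(unique(labels[!is.na(labels)]))
  out <- rep(NA_integer_, length(labels))
  for (i in seq_along(cls)) out[which(labels == cls[i])] <- i
  names(out) <- names(labels)
  out
}

#' Robust consensus clustering of an expression matrix
#'
#' Orchestrates the full procedure: choose PCA vs t-SNE by 2D grid entropy,
#' build the reduced-dimension views, sweep PAM over K, form the
#' co-clustering matrix, cut consensus blocks, and merge blocks without
#' differential expression. The result carries the labels (NA for cells
#' that reached no robust block), the co-clustering matrix, and a config
#' snapshot sufficient to reproduce the run.
#'
#' @param expr genes-by-cells expression matrix.
#' @param seed master seed; all stochastic stages (t-SNE) derive from it.
#' @param embedding `NULL` (choose by entropy) or "pca"/"tsne" to force.
#' @param n_var_genes,k_min,k_max,self_similarity,min_size,
#'   de_proportion_threshold,adj_p,bins_per_axis stage parameters; defaults
#'   are the procedure's standard values (500 variable genes, K from 5 to
#'   10, self-similarity 0.6, minimum block of 20 cells, merge below a 10%
#'   DE fraction at adjusted p < 0.05, 20x20 entropy grid).
#' @return object of class `robust_clustering`: list with `labels`,
#'   `cocluster`, `n_clusters`, `embedding`, `entropy` and `config`.
#' @export
robust_cluster <- function(expr, seed = 1L, embedding = NULL,
                           n_var_genes = 500L, k_min = 5L, k_max = 10L,
                           self_similarity = 0.6, min_size = 20L,
                           de_proportion_threshold = 0.1, adj_p = 0.05,
                           bins_per_axis = 20L) {
  expr <- validate_expression(expr)
  if (ncol(expr) < min_size)
    stop("fewer cells than the minimum cluster size")
  entropy <- c(pca = NA_real_, tsne = NA_real_)
  if (is.null(embedding)) {
    ce <- choose_embedding(expr, seed = seed, n_var_genes = n_var_genes,
                           bins_per_axis = bins_per_axis)
    embedding <- ce$choice
    entropy <- ce$entropy
  } else {
    embedding <- match.arg(embedding, c("pca", "tsne"))
  }
  views <- make_views(expr, embedding = embedding, seed = seed,
                      n_var_genes = n_var_genes)
  labelings <- pam_sweep(views, k_min = k_min, k_max = k_max)
  cc <- cocluster_matrix(labelings, cell_ids = colnames(expr))
  labels <- consensus_clusters(cc, self_similarity = self_similarity,
                               min_size = min_size)
  labels <- merge_similar_clusters(
    expr, labels, de_proportion_threshold = de_proportion_threshold,
    adj_p = adj_p, n_var_genes = n_var_genes)
  structure(list(
    labels = labels,
    cocluster = cc,
    n_clusters = length(unique(labels[!is.na(labels)])),
    embedding = embedding,
    entropy = entropy,
    config = list(seed = seed, n_var_genes = n_var_genes, k_min = k_min,
                  k_max = k_max, self_similarity = self_similarity,
                  min_size = min_size,
                  de_proportion_threshold = de_proportion_threshold,
                  adj_p = adj_p, bins_per_axis = bins_per_axis,
                  n_views = length(views), n_labelings = length(labelings))),
    class = "robust_clustering")
}

#' @export
print.robust_clustering <- function(x, ...) {
  cat(sprintf(
    "robust_clustering: %d cells, %d clusters, %.1f%% assigned (%s views)\n",
    length(x$labels), x$n_clusters,
    100 * proportion_robustly_clustered(x$labels), x$embedding))
  invisible(x)
}
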