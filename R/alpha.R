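# Data-driven choice of the smoothing strength alpha. The restart rate
# (1 - alpha) is the method's one free parameter; rather than fixing it, the
# scan smooths at every alpha on a grid, re-runs the robust clustering with
# the same master seed (so differences are attributable to alpha alone), and
# picks the alpha whose clustering assigns the most cells to robust
# clusters. An entropy-based alternative picks the alpha whose smoothed data
# yields the most informative 2D embedding. Neither criterion needs
# external labels.

#' Scan the smoothing parameter alpha by cluster robustness
#'
#' For each alpha on the grid (which should contain 0, the no-smoothing
#' baseline) the expression matrix is network-smoothed, robust-clustered,
#' and scored by the proportion of cells assigned to robust clusters and by
#' the 2D grid entropy of the chosen embedding. When external labels are
#' supplied, median cluster purity and AMI are recorded as well (for
#' evaluation only — they never drive the selection). The chosen alpha is
#' the argmax of the selected criterion; ties go to the smaller alpha (less
#' smoothing).
#'
#' @param expr genes-by-cells expression matrix.
#' @param network a [gene_network()] smoothing prior.
#' @param grid alpha values in \[0, 1) (default 0, 0.1, ..., 0.9).
#' @param seed master seed, reused for every alpha.
#' @param truth optional external per-cell labels.
#' @param criterion "robustness" (proportion in robust clusters) or
#'   "entropy" (2D embedding grid entropy).
#' @param ... passed to [robust_cluster()].
#' @return object of class `alpha_scan`: list with `table` (one row per
#'   alpha), `chosen_alpha`, `criterion` and `clusterings` (the per-alpha
#'   label vectors).
#' @export
scan_alpha <- function(expr, network, grid = seq(0, 0.9, by = 0.1),
                       seed = 1L, truth = NULL,
                       criterion = c("robustness", "entropy"), ...) {
  expr <- validate_expression(expr)
  criterion <- match.arg(criterion)
  stopifnot(all(grid >= 0 & grid < 1))
  grid <- sort(unique(grid))
  rows <- vector("list", length(grid))
  labs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    a <- grid[i]
    sm <- if (a == 0) expr else netsmooth(expr, network, alpha = a)
    rc <- robust_cluster(sm, seed = seed, ...)
    ent <- rc$entropy[rc$embedding]
    if (is.na(ent)) {  # embedding was forced; compute its entropy directly
      x <- t(log1p(select_variable_genes(sm, min(500L, nrow(sm)))))
      emb <- if (rc$embedding == "pca") stats::prcomp(x, rank. = 2L)$x
             else run_tsne(x, dims = 2L, seed = seed)
      ent <- embedding_grid_entropy(emb)
    }
    row <- data.frame(
      alpha = a,
      proportion_robust = proportion_robustly_clustered(rc$labels),
      n_clusters = rc$n_clusters,
      entropy_2d = unname(ent),
      embedding = rc$embedding,
      stringsAsFactors = FALSE)
    if (!is.null(truth)) {
      if (all(is.na(rc$labels))) {
        # a clustering that assigns no cells carries no information
        row$median_purity <- NA_real_
        row$ami <- 0
      } else {
        row$median_purity <- cluster_purity(rc$labels, truth)$median
        row$ami <- suppressWarnings(
          adjusted_mutual_information(rc$labels, truth))
      }
    }
    rows[[i]] <- row
    labs[[i]] <- rc$labels
  }
  tab <- do.call(rbind, rows)
  names(labs) <- as.character(grid)
  score <- switch(criterion,
                  robustness = tab$proportion_robust,
                  entropy = tab$entropy_2d)
  chosen <- grid[which.max(score)]  # grid ascending: ties -> smaller alpha
  structure(list(table = tab, chosen_alpha = chosen, criterion = criterion,
                 clusterings = labs, seed = seed),
            class = "alpha_scan")
}

#' @export
print.alpha_scan <- function(x, ...) {
  cat(sprintf("alpha_scan (%s criterion): chosen alpha = %.2g\n",
              x$criterion, x$chosen_alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pick alpha by 2D-embedding entropy
#'
#' Convenience wrapper around [scan_alpha()] with the entropy criterion:
#' returns the alpha whose smoothed data has the most informative 2D
#' embedding.
#'
#' @inheritParams scan_alpha
#' @return the chosen alpha (a single number from `grid`).
#' @export
pick_alpha_entropy <- function(expr, network, grid = seq(0, 0.9, by = 0.1),
                               seed = 1L, ...) {
  scan_alpha(expr, network, grid = grid, seed = seed,
             criterion = "entropy", ...)$chosen_alpha
}
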