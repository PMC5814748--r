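# Random-walk-with-restarts diffusion: a walker on the gene graph moves to a
# neighbour with probability alpha * (normalized edge weight) and restarts at
# its origin with probability (1 - alpha). The stationary distribution is a
# linear operator on the initial profile,
#   K = (1 - alpha) * (I - alpha * A)^-1,
# with A the column-normalized adjacency. Since the 1-norm of A is <= 1 and
# alpha < 1, I - alpha*A is always invertible.

#' Build the RWR smoothing kernel
#'
#' Computes `K = (1 - alpha) (I - alpha A)^-1` for a column-normalized
#' adjacency by a sparse LU solve (never an explicit inverse of an
#' ill-conditioned system). `alpha = 0` yields the identity: a perfect
#' restart rate and no smoothing. For an unsigned adjacency without zero
#' columns, K is column-stochastic, so smoothing conserves each cell's
#' total expression.
#'
#' @param adj a `normalized_adjacency` from [normalize_adjacency()].
#' @param alpha restart complement in \[0, 1); larger values diffuse signal
#'   farther across the network.
#' @return an object of class `smoothing_kernel` with elements `matrix`,
#'   `alpha` and `genes`.
#' @export
build_kernel <- function(adj, alpha) {
  stopifnot(inherits(adj, "normalized_adjacency"))
  check_alpha(alpha)
  n <- length(adj$genes)
  if (alpha == 0) {
    K <- Matrix::Diagonal(n)
  } else {
    S <- Matrix::Diagonal(n) - alpha * adj$matrix
    K <- tryCatch(
      (1 - alpha) * Matrix::solve(S, Matrix::Diagonal(n)),
      error = function(e)
        stop("linear system (I - alpha*A) could not be solved: ",
             conditionMessage(e)))
  }
  dimnames(K) <- list(adj$genes, adj$genes)
  structure(list(matrix = K, alpha = alpha, genes = adj$genes),
            class = "smoothing_kernel")
}

#' @export
print.smoothing_kernel <- function(x, ...) {
  cat(sprintf("smoothing_kernel: %d genes, alpha = %.3g\n",
              length(x$genes), x$alpha))
  invisible(x)
}

#' Iterative RWR smoothing
#'
#' Power iteration `f_{t+1} = alpha A f_t + (1 - alpha) f_0`, stopped when
#' the largest column-wise change drops below `tol`. Converges to the same
#' result as applying [build_kernel()]; provided as a cross-check and as a
#' memory-light path for very large gene sets.
#'
#' @param f0 genes-by-cells numeric matrix (the profiles to smooth).
#' @param adj a `normalized_adjacency` matching `f0`'s row order.
#' @param alpha restart complement in \[0, 1).
#' @param tol convergence tolerance on the max absolute change per step.
#' @param max_iter iteration cap; non-convergence raises a warning carrying
#'   the final residual, and the last iterate is still returned.
#' @return the smoothed matrix, with attributes `converged` (logical) and
#'   `iterations` (integer).
#' @export
smooth_iterative <- function(f0, adj, alpha, tol = 1e-9, max_iter = 1000L) {
  stopifnot(inherits(adj, "normalized_adjacency"), tol > 0, max_iter >= 1)
  check_alpha(alpha)
  f0 <- as.matrix(f0)
  if (nrow(f0) != length(adj$genes))
    stop("f0 must have one row per adjacency gene")
  A <- adj$matrix
  f <- f0
  restart <- (1 - alpha) * f0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    fn <- as.matrix(alpha * (A %*% f)) + restart
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "RWR iteration did not converge in %d steps (residual %.3g)",
      max_iter, delta))
  attr(f, "converged") <- converged
  attr(f, "iterations") <- iter
  dimnames(f) <- dimnames(f0)
  f
}

#' Network-smooth an expression matrix
#'
#' Applies the RWR kernel to every cell's expression profile: genes shared
#' between the matrix and the network (and connected within the shared
#' subnetwork) are smoothed, `E_sm = K E`; genes absent from the network, and
#' genes isolated within it, pass through unchanged. Row order and all
#' identifiers are preserved. The matrix is smoothed as given — library-size
#' normalization (and any log transform appropriate for downstream analyses)
#' is the caller's responsibility.
#'
#' @param expr nonnegative genes-by-cells numeric matrix with unique
#'   rownames (genes) and colnames (cells).
#' @param network a [gene_network()].
#' @param alpha restart complement in \[0, 1); 0 returns the input.
#' @param clip_negative set negative smoothed values to 0. Forced to `TRUE`
#'   for signed networks, whose inhibitory (negative) edges can push
#'   smoothed expression below zero.
#' @param verbose log the count of network-covered vs pass-through genes.
#' @return smoothed matrix of the same dimensions and dimnames as `expr`.
#' @export
netsmooth <- function(expr, network, alpha, clip_negative = network$signed,
                      verbose = FALSE) {
  expr <- validate_expression(expr)
  stopifnot(inherits(network, "gene_network"))
  check_alpha(alpha)
  shared <- intersect(rownames(expr), network$genes)
  if (length(shared) == 0L)
    stop(sprintf(paste0(
      "no genes shared between expression matrix and network ",
      "(expression ids look like '%s', network ids like '%s'); ",
      "check the identifier namespaces"),
      rownames(expr)[1], network$genes[1]))
  if (network$signed) clip_negative <- TRUE
  sub <- subset_to_genes(network, shared)
  deg <- network_degrees(sub)
  covered <- names(deg)[deg > 0]
  if (verbose)
    message(sprintf("smoothing %d network-covered genes; %d pass through",
                    length(covered), nrow(expr) - length(covered)))
  out <- expr
  if (length(covered) > 0L && alpha > 0) {
    adj <- normalize_adjacency(subset_to_genes(sub, covered))
    K <- build_kernel(adj, alpha)
    out[adj$genes, ] <- as.matrix(K$matrix %*% expr[adj$genes, , drop = FALSE])
  }
  if (clip_negative) out[out < 0] <- 0
  out
}
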