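#' Construct a gene network
#'
#' A `gene_network` holds a weighted (optionally signed, optionally directed)
#' gene-gene interaction graph used as the smoothing prior. Undirected edges
#' are stored once and symmetrized only when the adjacency matrix is built,
#' so that degree normalization does not double-count them.
#'
#' @param genes character vector of unique gene identifiers.
#' @param edges data.frame with columns `from`, `to`, `weight`. Self-loops
#'   are forbidden; duplicate (from, to) pairs are forbidden (collapse them
#'   before construction, as [load_edge_list()] does).
#' @param directed logical; if `FALSE` (default) each edge is interpreted
#'   symmetrically.
#' @param signed logical; if `FALSE` all weights must be strictly positive.
#'   Signed networks encode activating interactions as positive weights and
#'   inhibiting ones as negative weights.
#' @param modules optional integer vector (one entry per gene, named by gene)
#'   recording module membership; attached by the synthetic generator.
#' @return an object of class `gene_network`.
#' @export
gene_network <- function(genes, edges, directed = FALSE, signed = FALSE,
                         modules = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("gene identifiers must be unique")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$weight <- as.numeric(edges$weight)
    if (any(edges$from == edges$to))
      stop("self-loops are not allowed in a gene_network")
    key <- if (directed) paste(edges$from, edges$to, sep = "\r")
           else paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
                      sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed in a gene_network")
    if (!all(c(edges$from, edges$to) %in% genes))
      stop("edge endpoints must all appear in `genes`")
    if (!signed && any(edges$weight <= 0))
      stop("unsigned networks require strictly positive weights")
    if (any(!is.finite(edges$weight)))
      stop("edge weights must be finite")
  }
  structure(list(genes = genes, edges = edges, directed = directed,
                 signed = signed, modules = modules),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges (%s%s)\n",
              length(x$genes), nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              if (x$signed) ", signed" else ""))
  invisible(x)
}

#' Read a gene network from a delimited edge list
#'
#' Expects 2 or 3 columns: `gene_a`, `gene_b` and an optional numeric weight
#' (missing weight means 1.0). Duplicate pairs (including reversed pairs for
#' undirected networks) are collapsed keeping the maximum absolute weight;
#' self-loops are dropped with a warning.
#'
#' @param path path to a TSV/CSV edge list.
#' @param directed logical; treat edges as directed.
#' @param signed logical; allow negative weights.
#' @param header logical; whether the first row is a header.
#' @return a [gene_network()].
#' @export
load_edge_list <- function(path, directed = FALSE, signed = FALSE,
                           header = FALSE) {
  dt <- data.table::fread(path, header = header, colClasses = "character",
                          data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2L || ncol(dt) > 3L)
    stop(sprintf("edge list must have 2 or 3 columns, found %d in '%s'",
                 ncol(dt), path))
  from <- dt[[1]]
  to <- dt[[2]]
  if (ncol(dt) == 3L) {
    weight <- suppressWarnings(as.numeric(dt[[3]]))
    if (anyNA(weight)) {
      bad <- which(is.na(weight))[1]
      stop(sprintf("non-numeric weight '%s' at line %d of '%s'",
                   dt[[3]][bad], bad + as.integer(header), path))
    }
  } else {
    weight <- rep(1.0, nrow(dt))
  }
  if (anyNA(from) || anyNA(to) || any(from == "") || any(to == ""))
    stop(sprintf("malformed rows (empty gene id) in '%s'", path))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) from '%s'", sum(loops), path))
  }
  genes <- unique(c(from, to))
  from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  if (length(from)) {
    if (directed) {
      a <- from; b <- to
    } else {
      a <- pmin(from, to); b <- pmax(from, to)
    }
    key <- paste(a, b, sep = "\r")
    # collapse duplicates keeping maximum absolute weight
    o <- order(key, -abs(weight))
    keep <- !duplicated(key[o])
    edges <- data.frame(from = a[o][keep], to = b[o][keep],
                        weight = weight[o][keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  gene_network(genes, edges, directed = directed, signed = signed)
}

#' Keep only the most confident interactions
#'
#' Retains edges whose confidence score is strictly above the given quantile
#' of the edge-weight distribution (e.g. `quantile = 0.9` keeps the 10% most
#' confident interactions, the construction used for STRING combined scores).
#' Retained edges are reset to weight 1.0 so that the smoothing graph is
#' unweighted; isolated genes stay in the gene list.
#'
#' @param network a [gene_network()] whose weights are confidence scores.
#' @param quantile numeric in \[0, 1); 0 keeps every edge.
#' @return a [gene_network()] with filtered, unit-weight edges.
#' @export
filter_by_score_quantile <- function(network, quantile) {
  stopifnot(inherits(network, "gene_network"),
            is.numeric(quantile), length(quantile) == 1L,
            quantile >= 0, quantile < 1)
  if (nrow(network$edges) == 0L)
    stop("cannot filter a network with no edges")
  w <- network$edges$weight
  keep <- if (quantile <= 0) rep(TRUE, length(w))
          else w > stats::quantile(w, quantile, names = FALSE)
  edges <- network$edges[keep, , drop = FALSE]
  edges$weight <- rep(1.0, nrow(edges))
  gene_network(network$genes, edges, directed = network$directed,
               signed = network$signed, modules = network$modules)
}

# Column-normalize a weight matrix by the sum of absolute values;
# all-zero columns are left untouched.
normalize_columns <- function(W) {
  s <- Matrix::colSums(abs(W))
  nz <- s > 0
  if (any(nz))
    W[, nz] <- W[, nz, drop = FALSE] %*% Matrix::Diagonal(sum(nz), 1 / s[nz])
  W
}

#' Build the column-normalized adjacency matrix of a network
#'
#' Materializes the genes-by-genes weight matrix (symmetrized for undirected
#' networks) and divides each column by its sum of absolute weights, so each
#' gene's outgoing edge weights sum to 1 (in absolute value for signed
#' networks). Columns of isolated genes stay zero; the diagonal is zero.
#'
#' @param network a [gene_network()].
#' @return an object of class `normalized_adjacency` with elements `matrix`
#'   (a sparse `dgCMatrix`) and `genes` (the row/column gene order).
#' @export
normalize_adjacency <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$genes) == 0L)
    stop("network has no genes")
  n <- length(network$genes)
  idx <- stats::setNames(seq_len(n), network$genes)
  e <- network$edges
  if (nrow(e)) {
    i <- idx[e$to]; j <- idx[e$from]; x <- e$weight
    if (!network$directed) {
      i <- c(i, idx[e$from]); j <- c(j, idx[e$to]); x <- c(x, e$weight)
    }
    W <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  dimnames(W) <- list(network$genes, network$genes)
  structure(list(matrix = normalize_columns(W), genes = network$genes,
                 signed = network$signed),
            class = "normalized_adjacency")
}

#' @export
print.normalized_adjacency <- function(x, ...) {
  cat(sprintf("normalized_adjacency: %d genes, %d nonzero entries%s\n",
              length(x$genes), Matrix::nnzero(x$matrix),
              if (isTRUE(x$signed)) " (signed)" else ""))
  invisible(x)
}

#' Permute gene labels while keeping the graph structure
#'
#' Produces a null network for sensitivity analyses: the wiring (and hence
#' the degree sequence) is identical, but gene identifiers are reassigned by
#' a uniform random permutation, destroying the correspondence between graph
#' modules and biology.
#'
#' @param network a [gene_network()].
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return a [gene_network()] with permuted labels.
#' @export
shuffle_gene_labels <- function(network, seed) {
  stopifnot(inherits(network, "gene_network"))
  genes <- network$genes
  perm <- withr::with_seed(seed, sample(genes))
  map <- stats::setNames(perm, genes)
  e <- network$edges
  if (nrow(e)) {
    e$from <- unname(map[e$from])
    e$to <- unname(map[e$to])
    if (!network$directed) {
      a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
      e$from <- a; e$to <- b
    }
  }
  gene_network(genes, e, directed = network$directed, signed = network$signed)
}

#' Induced subgraph on a gene set
#'
#' @param network a [gene_network()].
#' @param keep character vector of gene identifiers to retain; genes absent
#'   from the network are ignored.
#' @return the induced [gene_network()] on `keep` intersected with the
#'   network's genes.
#' @export
subset_to_genes <- function(network, keep) {
  stopifnot(inherits(network, "gene_network"))
  keep <- intersect(network$genes, keep)
  if (length(keep) == 0L)
    stop("no overlap between `keep` and the network's genes")
  e <- network$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  modules <- network$modules
  if (!is.null(modules)) modules <- modules[names(modules) %in% keep]
  gene_network(keep, e, directed = network$directed, signed = network$signed,
               modules = modules)
}

#' Degree sequence of a network
#'
#' Number of incident edges per gene (in + out for directed networks).
#'
#' @param network a [gene_network()].
#' @return named integer vector over the network's genes.
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  d <- stats::setNames(integer(length(network$genes)), network$genes)
  tab <- table(c(network$edges$from, network$edges$to))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Persist a normalized adjacency as MatrixMarket plus a gene-order file
#'
#' Allows the (potentially expensive) kernel input to be precomputed once
#' and reloaded, keeping the heavy linear algebra off-line.
#'
#' @param adj a `normalized_adjacency`.
#' @param mtx_path output path for the MatrixMarket file.
#' @param genes_path output path for the gene-order file (one id per line).
#' @export
write_adjacency <- function(adj, mtx_path, genes_path) {
  stopifnot(inherits(adj, "normalized_adjacency"))
  Matrix::writeMM(methods::as(adj$matrix, "generalMatrix"), mtx_path)
  writeLines(adj$genes, genes_path)
  invisible(NULL)
}

#' @rdname write_adjacency
#' @param signed logical; mark the loaded adjacency as signed.
#' @return `read_adjacency` returns a `normalized_adjacency`.
#' @export
read_adjacency <- function(mtx_path, genes_path, signed = FALSE) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  if (length(genes) != nrow(m) || nrow(m) != ncol(m))
    stop("gene-order file does not match the adjacency dimensions")
  dimnames(m) <- list(genes, genes)
  structure(list(matrix = m, genes = genes, signed = signed),
            class = "normalized_adjacency")
}
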