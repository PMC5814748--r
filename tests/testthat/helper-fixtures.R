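# Shared fixtures, built in code at test time.

# two connected genes (g1 - g2) plus helpers
pair_network <- function() {
  gene_network(c("g1", "g2"),
               data.frame(from = "g1", to = "g2", weight = 1))
}

triangle_network <- function() {
  gene_network(c("g1", "g2", "g3"),
               data.frame(from = c("g1", "g1", "g2"),
                          to = c("g2", "g3", "g3"),
                          weight = 1))
}

# Erdos-Renyi-ish random unsigned network with every gene connected
random_connected_network <- function(n_genes, p = 0.15, seed = 1) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n_genes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    # guarantee no isolated genes: chain all genes together
    chain <- cbind(seq_len(n_genes - 1), 2:n_genes)
    idx <- unique(rbind(pairs[keep, , drop = FALSE], chain))
    w <- stats::runif(nrow(idx), 0.2, 1)
  })
  gene_network(genes,
               data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                          weight = w))
}

random_expression <- function(n_genes, n_cells, seed = 1, max_count = 50) {
  withr::with_seed(seed,
    matrix(stats::rpois(n_genes * n_cells, lambda = max_count / 5),
           n_genes, n_cells,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("c%03d", seq_len(n_cells)))))
}

write_tmp_edges <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(rows, path)
  path
}

# AMI that maps the degenerate no-assignment case to 0, as scan_alpha does
ami_or_zero <- function(labels, truth) {
  if (all(is.na(labels))) return(0)
  suppressWarnings(adjusted_mutual_information(labels, truth))
}
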