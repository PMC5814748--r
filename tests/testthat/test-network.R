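test_that("edge lists read back with duplicate collapse and self-loop drop", {
  p <- write_tmp_edges(c("g1\tg2", "g2\tg3"))
  net <- load_edge_list(p)
  expect_length(net$genes, 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$weight, c(1, 1))

  # duplicates (including reversed pairs) collapse to the max abs weight
  p <- write_tmp_edges(c("g1\tg2\t1.0", "g1\tg2\t0.5", "g2\tg1\t0.25"))
  net <- load_edge_list(p)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1.0)

  p <- write_tmp_edges(c("g1\tg1\t1.0"))
  expect_warning(net <- load_edge_list(p), "self-loop")
  expect_equal(length(net$genes), 1)
  expect_equal(nrow(net$edges), 0)

  p <- write_tmp_edges(c("g1\tg2\tnot_a_number"))
  expect_error(load_edge_list(p), "non-numeric weight.*line 1")
})

test_that("score-quantile filter keeps the top edges and unit-weights them", {
  genes <- sprintf("g%02d", 1:11)
  net <- gene_network(genes,
                      data.frame(from = genes[1:10], to = genes[2:11],
                                 weight = 1:10))
  kept <- filter_by_score_quantile(net, 0.9)
  expect_equal(nrow(kept$edges), 1)
  expect_equal(kept$edges$from, "g10")  # the weight-10 edge survives
  expect_equal(kept$edges$weight, 1.0)
  expect_length(kept$genes, 11)  # isolated genes retained

  expect_equal(nrow(filter_by_score_quantile(net, 0)$edges), 10)
  expect_error(filter_by_score_quantile(
    gene_network("g1", data.frame()[0, ]), 0.5), "no edges")

  # 1000 random-weight edges vs an independent sort-based oracle
  n <- 1000
  withr::with_seed(99, w <- stats::runif(n))
  from <- sprintf("a%04d", seq_len(n))
  to <- sprintf("b%04d", seq_len(n))
  big <- gene_network(c(from, to),
                      data.frame(from = from, to = to, weight = w))
  flt <- filter_by_score_quantile(big, 0.9)
  # oracle: sort weights, keep edges ranked strictly inside the top decile
  ord <- order(w, decreasing = TRUE)
  n_top <- sum(w > w[ord][round(0.1 * n) + 1])
  expect_equal(nrow(flt$edges), n_top)
  expect_setequal(flt$edges$from, from[ord][seq_len(n_top)])
})

test_that("adjacency normalization matches hand-computed cases", {
  A <- as.matrix(normalize_adjacency(pair_network())$matrix)
  expect_equal(A, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  # star: hub column spreads 1/3 to each leaf; leaf columns point at hub
  star <- gene_network(c("h", "g1", "g2", "g3"),
                       data.frame(from = "h", to = c("g1", "g2", "g3"),
                                  weight = 1))
  A <- as.matrix(normalize_adjacency(star)$matrix)
  expect_equal(A[c("g1", "g2", "g3"), "h"], rep(1 / 3, 3),
               ignore_attr = TRUE)
  expect_equal(A["h", "g1"], 1)
  expect_equal(unname(diag(A)), rep(0, 4))

  # signed: columns normalized by the sum of absolute weights
  sgn <- gene_network(c("g1", "g2", "g3"),
                      data.frame(from = c("g1", "g1"), to = c("g2", "g3"),
                                 weight = c(-1, 1)),
                      directed = TRUE, signed = TRUE)
  A <- as.matrix(normalize_adjacency(sgn)$matrix)
  expect_equal(A[c("g2", "g3"), "g1"], c(-0.5, 0.5), ignore_attr = TRUE)
})

test_that("normalization is idempotent and columns sum to one", {
  for (seed in 1:3) {
    net <- random_connected_network(30, seed = seed)
    A <- normalize_adjacency(net)$matrix
    expect_lt(max(abs(Matrix::colSums(abs(A)) - 1)), 1e-10)
    A2 <- rwrsmooth:::normalize_columns(A)
    expect_lt(max(abs(A - A2)), 1e-12)
    expect_equal(unname(Matrix::diag(A)), rep(0, 30))
  }
})

test_that("label shuffling preserves structure and is seed-deterministic", {
  net <- random_connected_network(40, seed = 5)
  sh <- shuffle_gene_labels(net, seed = 11)
  expect_setequal(sh$genes, net$genes)
  expect_equal(nrow(sh$edges), nrow(net$edges))
  expect_equal(sort(unname(network_degrees(sh))),
               sort(unname(network_degrees(net))))
  expect_identical(sh$edges, shuffle_gene_labels(net, seed = 11)$edges)
  expect_false(identical(sh$edges, net$edges))
})

test_that("gene subsetting is the induced subgraph", {
  tri <- triangle_network()
  expect_equal(nrow(subset_to_genes(tri, tri$genes)$edges), 3)
  sub <- subset_to_genes(tri, c("g1", "g2"))
  expect_equal(nrow(sub$edges), 1)
  expect_setequal(c(sub$edges$from, sub$edges$to), c("g1", "g2"))
  expect_error(subset_to_genes(tri, "nope"), "no overlap")

  net <- random_connected_network(50, seed = 3)
  keep <- withr::with_seed(4, sample(net$genes, 20))
  sub <- subset_to_genes(net, keep)
  oracle <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ]
  expect_equal(nrow(sub$edges), nrow(oracle))
  expect_setequal(paste(sub$edges$from, sub$edges$to),
                  paste(oracle$from, oracle$to))
})

test_that("normalized adjacency round-trips through MatrixMarket", {
  net <- random_connected_network(25, seed = 8)
  adj <- normalize_adjacency(net)
  mtx <- withr::local_tempfile(fileext = ".mtx")
  gns <- withr::local_tempfile(fileext = ".txt")
  write_adjacency(adj, mtx, gns)
  back <- read_adjacency(mtx, gns)
  expect_equal(back$genes, adj$genes)
  expect_lt(max(abs(back$matrix - adj$matrix)), 1e-12)
})
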