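test_that("variable-gene selection matches a brute-force variance sort", {
  expr <- random_expression(50, 30, seed = 51)
  expr["g007", ] <- 4  # constant gene: zero variance, ranked last
  sel <- select_variable_genes(expr, 10)
  v <- apply(log1p(expr), 1, var)
  oracle <- names(sort(v, decreasing = TRUE))[1:10]
  expect_setequal(rownames(sel), oracle)
  expect_false("g007" %in% rownames(select_variable_genes(expr, 49)))
  # original row order preserved among the selected
  expect_identical(rownames(sel),
                   rownames(expr)[rownames(expr) %in% oracle])
  expect_identical(select_variable_genes(expr, 50), expr)
  expect_error(select_variable_genes(expr, 51), "exceeds")
})

test_that("the view menu follows the chosen embedding", {
  expr <- random_expression(1100, 60, seed = 52)
  vp <- make_views(expr, "pca", seed = 1)
  expect_named(vp, c("pca5", "pca15", "pca50",
                     "top100", "top500", "top1000"))
  # PCA scores have orthogonal columns
  cp <- crossprod(vp$pca15)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)

  vt <- make_views(expr, "tsne", seed = 1)
  expect_named(vt, c("tsne2", "tsne3", "top100", "top500", "top1000"))
  expect_equal(ncol(vt$tsne3), 3)

  # views needing more components than cells are dropped with a warning
  small <- random_expression(200, 40, seed = 53)
  expect_warning(v <- make_views(small, "pca", seed = 1), "dropping PCA view")
  expect_false("pca50" %in% names(v))
  # top-gene counts capped at the gene number collapse duplicate views
  expect_named(v, c("pca5", "pca15", "top100", "top200"))
})

test_that("pam sweep produces one labeling per view-K pair", {
  expr <- random_expression(80, 40, seed = 54)
  views <- make_views(expr, "pca", seed = 1, pca_dims = c(5L, 15L),
                      top_counts = c(20L, 50L))
  labelings <- pam_sweep(views, k_min = 5, k_max = 10)
  expect_length(labelings, length(views) * 6)
  expect_true(all(vapply(labelings, function(l)
    length(unique(l)), integer(1)) >= 5))
  expect_error(pam_sweep(views, k_min = 5, k_max = 50), "more cells")
})

test_that("pam separates well-separated blobs exactly at the true K", {
  withr::with_seed(55, {
    blob1 <- matrix(rnorm(20 * 2), 10, 2) + 10
    blob2 <- matrix(rnorm(20 * 2), 10, 2) - 10
  })
  x <- rbind(blob1, blob2)
  labels <- pam_sweep(list(v = x), k_min = 2, k_max = 2)[[1]]
  expect_length(unique(labels[1:10]), 1)
  expect_length(unique(labels[11:20]), 1)
  expect_false(labels[1] == labels[11])
})

test_that("co-clustering matrix equals brute-force pair counting", {
  l1 <- c(1, 1, 2, 2)
  expect_equal(cocluster_matrix(list(l1)),
               outer(l1, l1, "==") * 1, ignore_attr = TRUE)
  l2 <- c(1, 2, 2, 2)
  cc <- cocluster_matrix(list(l1, l2))
  expect_equal(cc[1, 2], 0.5)  # together in one of two labelings
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)

  withr::with_seed(56, labelings <- replicate(7, sample(1:3, 25, replace = TRUE),
                                              simplify = FALSE))
  cc <- cocluster_matrix(labelings)
  oracle <- matrix(0, 25, 25)
  for (l in labelings)
    for (i in 1:25) for (j in 1:25)
      oracle[i, j] <- oracle[i, j] + (l[i] == l[j]) / 7
  expect_equal(cc, oracle, tolerance = 1e-12)
  expect_true(isSymmetric(cc))
  expect_true(all(cc >= 0 & cc <= 1))
})

test_that("consensus emits blocks meeting both similarity and size rules", {
  # two perfect blocks of 20: exactly two clusters, nobody unassigned
  cc <- matrix(0, 40, 40)
  cc[1:20, 1:20] <- 1
  cc[21:40, 21:40] <- 1
  labels <- consensus_clusters(cc, self_similarity = 0.6, min_size = 20)
  expect_equal(length(unique(labels)), 2)
  expect_false(anyNA(labels))
  expect_length(unique(labels[1:20]), 1)
  expect_length(unique(labels[21:40]), 1)

  # a perfect block one cell short of min_size is wholly unassigned
  cc <- matrix(0, 39, 39)
  cc[1:20, 1:20] <- 1
  cc[21:39, 21:39] <- 1
  labels <- consensus_clusters(cc, self_similarity = 0.6, min_size = 20)
  expect_true(all(!is.na(labels[1:20])))
  expect_true(all(is.na(labels[21:39])))

  expect_error(consensus_clusters(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(consensus_clusters(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("consensus agrees with an exhaustive dendrogram-cut oracle", {
  # noisy two-block co-clustering on 12 cells, small min_size
  withr::with_seed(57, {
    cc <- matrix(runif(144, 0, 0.25), 12, 12)
    cc[1:6, 1:6] <- cc[1:6, 1:6] + 0.7
    cc[7:12, 7:12] <- cc[7:12, 7:12] + 0.7
  })
  cc <- pmin((cc + t(cc)) / 2, 1)
  diag(cc) <- 1
  labels <- consensus_clusters(cc, self_similarity = 0.6, min_size = 3)

  # oracle: enumerate every subtree of the dendrogram, keep qualifying ones,
  # and retain the maximal qualifying subtrees (no qualifying ancestor)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  subtrees <- list()
  for (node in seq_len(nrow(hc$merge))) {
    mem <- integer()
    stack <- node
    while (length(stack)) {
      nd <- stack[1]; stack <- stack[-1]
      for (child in hc$merge[nd, ])
        if (child < 0) mem <- c(mem, -child) else stack <- c(stack, child)
    }
    subtrees[[node]] <- sort(mem)
  }
  ok <- vapply(subtrees, function(mem) {
    m <- cc[mem, mem]
    length(mem) >= 3 && mean(m[upper.tri(m)]) >= 0.6
  }, logical(1))
  maximal <- which(ok & !vapply(seq_along(subtrees), function(i)
    any(ok & vapply(subtrees, function(s)
      length(s) > length(subtrees[[i]]) && all(subtrees[[i]] %in% s),
      logical(1))), logical(1)))
  oracle_labels <- rep(NA_integer_, 12)
  for (k in seq_along(maximal)) oracle_labels[subtrees[[maximal[k]]]] <- k
  same_partition <- function(a, b) {
    identical(is.na(a), is.na(b)) &&
      all(outer(a, a, "==") == outer(b, b, "=="), na.rm = TRUE)
  }
  expect_true(same_partition(labels, oracle_labels))
})

test_that("clusters with no differential expression merge; shifted ones do not", {
  # two 'clusters' drawn from the same distribution collapse into one
  withr::with_seed(58, {
    expr <- matrix(rnbinom(200 * 60, mu = 8, size = 2), 200, 60)
  })
  dimnames(expr) <- list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:60))
  labels <- rep(1:2, each = 30)
  merged <- merge_similar_clusters(expr, labels)
  expect_equal(length(unique(merged)), 1)

  # 40% of genes shifted by ~3 SD in cluster 2: the pair must survive
  expr2 <- expr
  withr::with_seed(59, shifted <- sample(200, 80))
  expr2[shifted, 31:60] <- expr2[shifted, 31:60] +
    ceiling(3 * sqrt(8 + 8^2 / 2))
  kept <- merge_similar_clusters(expr2, labels)
  expect_equal(length(unique(kept)), 2)

  # single cluster input returned unchanged; unassigned stay unassigned
  one <- c(rep(1L, 30), rep(NA_integer_, 30))
  expect_equal(merge_similar_clusters(expr, one), one)
})

test_that("robust clustering recovers well-separated types end to end", {
  net <- generate_network(300, 6, 0.2, 0.01, seed = 7001L)
  d <- generate_counts(net, 180, 6, libsize = 3000, nb_dispersion = 0.2,
                       fold_change = 5, dropout_midpoint = -4,
                       dropout_steepness = 1.0, seed = 501L)
  rc <- robust_cluster(d$counts, seed = 3)
  expect_equal(rc$n_clusters, 6)
  expect_gte(proportion_robustly_clustered(rc$labels), 0.9)
  expect_gte(adjusted_mutual_information(rc$labels, d$true_labels), 0.9)

  # determinism under the master seed
  rc2 <- robust_cluster(d$counts, seed = 3)
  expect_identical(rc$labels, rc2$labels)
  expect_equal(rc$cocluster, rc2$cocluster)

  # structureless data: nothing (or one blob) should emerge
  d0 <- generate_counts(net, 150, 3, libsize = 1000, nb_dispersion = 0.8,
                        fold_change = 1.0, dropout_midpoint = -1,
                        dropout_steepness = 1.0, seed = 502L)
  rc0 <- robust_cluster(d0$counts, seed = 3)
  expect_lte(rc0$n_clusters, 1)
})

test_that("co-clustering invariants hold on a real pipeline run", {
  d <- benchmark_instance("easy")
  rc <- robust_cluster(d$counts, seed = 2)
  cc <- rc$cocluster
  expect_true(isSymmetric(unname(cc)))
  expect_equal(unname(diag(cc)), rep(1, ncol(d$counts)))
  expect_true(all(cc >= 0 & cc <= 1))
  tabs <- table(rc$labels)
  expect_true(all(tabs >= rc$config$min_size))
})
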