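test_that("PCA embeddings match a brute-force eigendecomposition oracle", {
  set.seed(31)
  v <- matrix(abs(rnorm(20)), 5, 4)
  nm <- toy_normalized(v)
  p <- run_pca(nm, colnames(nm), n_pcs = 3, clip = 100)
  # oracle: z-score, center, eigendecompose the covariance matrix
  z <- scale(v)
  z <- sweep(z, 2, colMeans(z), "-")
  eig <- eigen(cov(z))
  for (j in 1:3) {
    vec <- eig$vectors[, j]
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    expect_equal(unname(p$gene_loadings[, j]), unname(vec), tolerance = 1e-8)
    expect_equal(unname(p$cell_embeddings[, j]), unname(drop(z %*% vec)),
                 tolerance = 1e-8)
    expect_equal(p$explained_variance[j], eig$values[j], tolerance = 1e-8)
  }
})

test_that("PCA respects the rank of planar data and rejects n_pcs beyond it", {
  set.seed(32)
  scores <- matrix(rnorm(40), 20, 2)
  load2 <- matrix(rnorm(20), 2, 10)
  v <- scores %*% load2
  v <- v - min(v)  # shift to non-negative; rank <= 3 (plane + offset)
  nm <- toy_normalized(v)
  p <- run_pca(nm, colnames(nm), n_pcs = 2, clip = 1e6)
  expect_length(p$explained_variance, 2)
  # centering removes the offset: everything beyond PC2 is numerically null
  expect_error(run_pca(nm, colnames(nm), n_pcs = 5, clip = 1e6), "rank")
})

test_that("duplicating every cell leaves loadings unchanged", {
  set.seed(33)
  v <- matrix(abs(rnorm(60)), 10, 6)
  nm1 <- toy_normalized(v)
  v2 <- rbind(v, v)
  rownames(v2) <- sprintf("c%02d", 1:20)
  nm2 <- toy_normalized(v2)
  p1 <- run_pca(nm1, colnames(nm1), n_pcs = 3, clip = 1e6)
  p2 <- run_pca(nm2, colnames(nm2), n_pcs = 3, clip = 1e6)
  expect_equal(p1$gene_loadings, p2$gene_loadings, tolerance = 1e-8)
})

test_that("SNN weights equal the brute-force set-arithmetic oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(10:50, 1)
    emb <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(sprintf("c%03d", 1:n), NULL))
    k <- sample(3:8, 1)
    g <- build_snn_graph(emb, k = k, prune = 1 / 15)
    oracle <- snn_bruteforce(emb, k, 1 / 15)
    adj <- as.matrix(igraph::as_adjacency_matrix(g$graph, attr = "weight"))
    expect_equal(unname(adj), unname(oracle), tolerance = 1e-12,
                 info = sprintf("seed %d n %d k %d", seed, n, k))
  }
})

test_that("coincident cells share full neighborhoods and separated clouds never connect", {
  emb <- rbind(matrix(0, 2, 2), matrix(5 + rnorm(8, sd = 0.01), 4, 2))
  rownames(emb) <- sprintf("c%d", 1:6)
  g <- build_snn_graph(emb, k = 2, prune = 0)
  adj <- as.matrix(igraph::as_adjacency_matrix(g$graph, attr = "weight"))
  expect_equal(adj["c1", "c2"], 1)  # identical points, identical neighbor sets

  set.seed(4)
  clouds <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
                  matrix(rnorm(40, 100, 0.5), 20, 2))
  rownames(clouds) <- sprintf("c%02d", 1:40)
  g2 <- build_snn_graph(clouds, k = 5, prune = 0)
  adj2 <- as.matrix(igraph::as_adjacency_matrix(g2$graph, attr = "weight"))
  expect_true(all(adj2[1:20, 21:40] == 0))
  expect_error(build_snn_graph(clouds, k = 40), "smaller than the number")
  expect_error(build_snn_graph(clouds, k = 0), "positive")
})

test_that("disconnected cliques cluster apart; vanishing resolution merges a connected graph", {
  # two tight clouds whose SNN graphs are complete cliques of weight 1
  set.seed(5)
  clouds <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
                  matrix(rnorm(20, 100, 0.01), 10, 2))
  rownames(clouds) <- sprintf("c%02d", 1:20)
  g <- build_snn_graph(clouds, k = 10, prune = 1 / 15)
  lab <- cluster_graph(g, resolution = 1.0, seed = 1)
  expect_equal(length(unique(lab$labels)), 2L)
  expect_equal(length(unique(lab$labels[1:10])), 1L)
  expect_equal(length(unique(lab$labels[11:20])), 1L)

  one <- matrix(rnorm(60), 30, 2, dimnames = list(sprintf("c%02d", 1:30), NULL))
  g1 <- build_snn_graph(one, k = 15, prune = 0)
  lab1 <- cluster_graph(g1, resolution = 0.01, seed = 1)
  expect_equal(length(unique(lab1$labels)), 1L)
})

test_that("clustering recovers planted populations and ignores cell order", {
  bench <- small_benchmark()
  nm <- bench$nm
  vg <- select_variable_genes(nm)
  p <- run_pca(nm, vg, n_pcs = 12)
  g <- build_snn_graph(p, k = 20)
  lab <- cluster_graph(g, resolution = 0.5, seed = 1)
  ari <- mclust::adjustedRandIndex(lab$labels, bench$truth)
  expect_gte(ari, 0.9)

  # permuting the input cells changes nothing up to relabeling
  set.seed(99)
  perm <- sample(rownames(nm))
  nm_p <- normalized_matrix(unclass(nm)[perm, ],
                            scale_factor = attr(nm, "scale_factor"))
  p2 <- run_pca(nm_p, vg, n_pcs = 12)
  g2 <- build_snn_graph(p2, k = 20)
  lab2 <- cluster_graph(g2, resolution = 0.5, seed = 1)
  expect_equal(mclust::adjustedRandIndex(lab2$labels[names(lab$labels)],
                                         lab$labels), 1)
})

test_that("tSNE returns deterministic 2-D coordinates and validates perplexity", {
  set.seed(6)
  v <- matrix(abs(rnorm(100 * 5)), 100, 5)
  nm <- toy_normalized(v)
  p <- run_pca(nm, colnames(nm), n_pcs = 3, clip = 1e6)
  y1 <- run_tsne(p, iterations = 100, seed = 2, perplexity = 10)
  y2 <- run_tsne(p, iterations = 100, seed = 2, perplexity = 10)
  expect_equal(dim(y1), c(100L, 2L))
  expect_identical(y1, y2)
  expect_error(run_tsne(p, perplexity = 200), "perplexity")
})
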