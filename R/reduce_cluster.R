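#' Principal component analysis over variable genes
#'
#' Each variable gene is z-scored across cells (mean 0, sd 1; zero-variance
#' genes are set to 0), values are clipped to `+/- clip`, and an exact PCA
#' is computed by singular value decomposition. Component signs are fixed
#' by making the largest-magnitude gene loading of each component positive,
#' so the result is bit-reproducible.
#'
#' @param nm A [normalized_matrix].
#' @param genes A `variable_gene_set`, [gene_list], or character vector of
#'   genes to use.
#' @param n_pcs Number of components to keep; must not exceed the rank of
#'   the scaled matrix.
#' @param clip Magnitude at which z-scores are clipped (default 10).
#' @return An object of class `pca_result`: list with `cell_embeddings`
#'   (cells x n_pcs), `gene_loadings` (genes x n_pcs), and
#'   `explained_variance` per component (decreasing).
#' @export
run_pca <- function(nm, genes, n_pcs = 12, clip = 10) {
  stopifnot(inherits(nm, "normalized_matrix"), n_pcs >= 1, clip > 0)
  gene_vec <- if (is.character(genes)) genes
  else if (inherits(genes, "gene_list")) genes$genes
  else genes$genes
  if (!length(gene_vec)) stop("no genes supplied for PCA")
  missing <- setdiff(gene_vec, colnames(nm))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  v <- unclass(nm)[, gene_vec, drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  z <- sweep(v, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  # re-center after clipping so the SVD decomposes the covariance exactly
  z <- sweep(z, 2, colMeans(z), "-")
  sv <- svd(z)
  rank <- sum(sv$d > max(dim(z)) * max(sv$d) * .Machine$double.eps)
  if (n_pcs > rank)
    stop(sprintf("n_pcs = %d exceeds matrix rank %d", n_pcs, rank))
  d <- sv$d[seq_len(n_pcs)]
  u <- sv$u[, seq_len(n_pcs), drop = FALSE]
  w <- sv$v[, seq_len(n_pcs), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(w[, j]))
    if (w[i, j] < 0) { w[, j] <- -w[, j]; u[, j] <- -u[, j] }
  }
  emb <- u %*% diag(d, n_pcs)
  dimnames(emb) <- list(rownames(v), paste0("PC", seq_len(n_pcs)))
  dimnames(w) <- list(gene_vec, paste0("PC", seq_len(n_pcs)))
  structure(list(cell_embeddings = emb, gene_loadings = w,
                 explained_variance = d^2 / (nrow(z) - 1)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d cells, %d genes, %d components\n",
              nrow(x$cell_embeddings), nrow(x$gene_loadings),
              ncol(x$cell_embeddings)))
  cat("  explained variance:",
      paste(sprintf("%.3g", utils::head(x$explained_variance, 6)), collapse = " "),
      "\n")
  invisible(x)
}

#' Build a shared-nearest-neighbor (SNN) graph
#'
#' For each cell, its `k` nearest neighbors by Euclidean distance in PC
#' space are found (each cell is included in its own neighbor list, the
#' usual SNN convention). The edge weight between cells i and j is the
#' Jaccard overlap of their neighbor sets,
#' `|N(i) n N(j)| / |N(i) u N(j)|`; edges with weight at or below `prune`
#' are removed.
#'
#' @param p A `pca_result` (or a numeric cells x dims matrix).
#' @param k Neighborhood size, `1 <= k < n_cells`.
#' @param prune Jaccard weight at or below which edges are dropped
#'   (default 1/15).
#' @return An object of class `snn_graph`: list with the `igraph` object
#'   (`graph`), `cell_ids`, `k` and `prune`.
#' @export
build_snn_graph <- function(p, k = 20, prune = 1 / 15) {
  emb <- if (inherits(p, "pca_result")) p$cell_embeddings else as.matrix(p)
  n <- nrow(emb)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(emb))
  # neighbor lists: k nearest including self; ties broken by cell index
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n))
    nbr[i, ] <- order(d[i, ], seq_len(n))[seq_len(k)]
  # shared-neighbor counts via indicator matrix product
  ind <- matrix(0L, n, n)
  ind[cbind(rep(seq_len(n), each = k), as.integer(t(nbr)))] <- 1L
  shared <- tcrossprod(ind)
  jac <- shared / (2 * k - shared)
  diag(jac) <- 0
  jac[jac <= prune] <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- rownames(emb)
  structure(list(graph = g, cell_ids = rownames(emb), k = k, prune = prune),
            class = "snn_graph")
}

#' @export
print.snn_graph <- function(x, ...) {
  cat(sprintf("snn_graph: %d cells, %d edges (k = %d, prune = %.4f)\n",
              length(x$cell_ids), igraph::ecount(x$graph), x$k, x$prune))
  invisible(x)
}

#' Modularity clustering of an SNN graph
#'
#' Louvain multilevel modularity optimization with a resolution parameter
#' scaling the null-model term. Deterministic given `seed`. Cells in
#' singleton components receive their own labels. Labels are relabeled to
#' be contiguous from 0, ordered by decreasing cluster size (ties by first
#' cell index).
#'
#' @param g An `snn_graph`.
#' @param resolution Positive resolution; higher values yield more, smaller
#'   clusters.
#' @param seed Integer seed.
#' @return A [cluster_assignment].
#' @export
cluster_graph <- function(g, resolution = 1.35, seed = 1L) {
  stopifnot(inherits(g, "snn_graph"))
  if (length(g$cell_ids) == 0) stop("empty graph")
  set.seed(seed)
  comm <- igraph::cluster_louvain(g$graph, resolution = resolution)
  memb <- igraph::membership(comm)
  # relabel contiguous from 0, largest cluster first
  tab <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- names(tab)[order(-as.integer(tab), first[names(tab)])]
  relab <- stats::setNames(seq_along(ord) - 1L, ord)
  labels <- stats::setNames(relab[as.character(memb)], g$cell_ids)
  cluster_assignment(labels, resolution = resolution, seed = seed)
}

#' t-SNE embedding of the PC space
#'
#' Two-dimensional t-stochastic neighbor embedding of the cell embeddings,
#' for visualization only. Deterministic given `seed`. Requires the Rtsne
#' package.
#'
#' @param p A `pca_result`.
#' @param iterations Number of gradient-descent iterations (default 1000).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n_cells - 1`.
#' @return A cells x 2 numeric matrix of coordinates.
#' @export
run_tsne <- function(p, iterations = 1000, seed = 1L, perplexity = 30) {
  stopifnot(inherits(p, "pca_result"))
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("run_tsne requires the Rtsne package")
  n <- nrow(p$cell_embeddings)
  if (perplexity >= n)
    stop("perplexity must be smaller than the number of cells")
  set.seed(seed)
  fit <- Rtsne::Rtsne(p$cell_embeddings, dims = 2, pca = FALSE,
                      perplexity = perplexity, max_iter = iterations,
                      check_duplicates = FALSE)
  out <- fit$Y
  dimnames(out) <- list(rownames(p$cell_embeddings), c("tSNE1", "tSNE2"))
  out
}
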