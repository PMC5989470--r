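# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (pair enumeration, set
# arithmetic, eigendecomposition) and share no code with the package
# internals they check.

# AUC by exhaustive pair counting with half credit for ties.
auc_bruteforce <- function(x_in, x_out) {
  tot <- 0
  for (a in x_in) for (b in x_out)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(x_in) * length(x_out))
}

# SNN Jaccard weights by explicit set arithmetic; neighbor lists are the k
# nearest points (self included), ties broken by point index.
snn_bruteforce <- function(emb, k, prune) {
  n <- nrow(emb)
  d <- as.matrix(dist(emb))
  nbrs <- lapply(seq_len(n), function(i) order(d[i, ], seq_len(n))[seq_len(k)])
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    jac <- length(intersect(nbrs[[i]], nbrs[[j]])) /
      length(union(nbrs[[i]], nbrs[[j]]))
    w[i, j] <- if (jac > prune) jac else 0
  }
  w
}

# Cohen's d from first principles.
cohens_d_oracle <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# Zero-inflated-normal log likelihood written out longhand (MLE
# parameters, sigma floored at 1 for degenerate positive sets).
zin_loglik_oracle <- function(x) {
  pos <- x[x > 0]
  pi_hat <- length(pos) / length(x)
  ll <- 0
  for (v in x) {
    if (v == 0) {
      ll <- ll + log(1 - pi_hat)
    } else {
      mu <- mean(pos)
      s <- if (length(pos) >= 2) sqrt(sum((pos - mu)^2) / length(pos)) else 0
      if (s <= 0) s <- 1
      ll <- ll + log(pi_hat) + dnorm(v, mu, s, log = TRUE)
    }
  }
  ll
}

# A tiny count matrix whose cells hit prescribed UMI totals while keeping
# a prescribed number of detected genes (for QC boundary tests).
toy_umi_matrix <- function(umi_totals, n_detected = 450, n_genes = 460) {
  stopifnot(all(umi_totals >= n_detected))
  m <- matrix(0, length(umi_totals), n_genes,
              dimnames = list(sprintf("c%02d", seq_along(umi_totals)),
                              sprintf("g%03d", seq_len(n_genes))))
  for (i in seq_along(umi_totals)) {
    m[i, seq_len(n_detected - 1)] <- 1
    m[i, n_detected] <- umi_totals[i] - (n_detected - 1)
  }
  count_matrix(m)
}

# Direct normalized_matrix builder for statistic-level tests.
toy_normalized <- function(values, scale_factor = 10000) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  normalized_matrix(values, scale_factor = scale_factor)
}

toy_labels <- function(labels, ids = sprintf("c%02d", seq_along(labels))) {
  cluster_assignment(setNames(labels, ids))
}

# Shared small synthetic benchmark (generated once per test run).
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_counts(synthetic_benchmark_spec(n_cells = 600, rng_seed = 101))
      f <- filter_cells_genes(sim$counts)
      nm <- normalize_log_scaled(f)
      cache <<- list(sim = sim, nm = nm,
                     truth = sim$ground_truth$labels[rownames(nm)])
    }
    cache
  }
})
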