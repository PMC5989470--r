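#' ROC-AUC marker test for one cluster versus the rest
#'
#' For every gene, the area under the ROC curve for separating in-cluster
#' from out-of-cluster cells by expression, computed exactly through the
#' rank (Mann-Whitney) identity with half credit for ties:
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_in * n_out)`.
#' Records for all genes are returned; callers filter by threshold.
#'
#' @param nm A [normalized_matrix].
#' @param labels A [cluster_assignment] covering the cells of `nm`.
#' @param cluster_id Integer label of the cluster of interest.
#' @return A data frame with one row per gene: `gene`, `cluster`, `auc`,
#'   `mean_in`, `mean_out` (mean normalized expression inside/outside) and
#'   `pct_in`, `pct_out` (detection fractions), sorted by decreasing AUC.
#' @export
roc_auc_marker <- function(nm, labels, cluster_id) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(labels, "cluster_assignment"))
  lab <- labels$labels[rownames(nm)]
  if (anyNA(lab)) stop("labels missing for some cells of the matrix")
  inside <- lab == cluster_id
  n_in <- sum(inside); n_out <- sum(!inside)
  if (n_in == 0) stop("cluster ", cluster_id, " has no cells")
  if (n_out == 0) stop("cluster ", cluster_id, " contains every cell")
  v <- unclass(nm)
  auc <- vapply(seq_len(ncol(v)), function(j) {
    r <- rank(v[, j])  # average ranks give the 0.5 tie credit exactly
    (sum(r[inside]) - n_in * (n_in + 1) / 2) / (n_in * n_out)
  }, numeric(1))
  vi <- v[inside, , drop = FALSE]
  vo <- v[!inside, , drop = FALSE]
  out <- data.frame(gene = colnames(v), cluster = cluster_id, auc = auc,
                    mean_in = colMeans(vi), mean_out = colMeans(vo),
                    pct_in = colMeans(vi > 0), pct_out = colMeans(vo > 0),
                    row.names = NULL)
  out[order(-out$auc, out$gene), , drop = FALSE]
}

# log-likelihood of expression values under a zero-inflated normal:
# point mass at zero with probability 1 - pi, normal over positive values.
# MLE parameters; sigma floored at 1 when positives are <2 or degenerate.
bimod_loglik <- function(x) {
  n <- length(x)
  pos <- x[x > 0]
  np <- length(pos)
  pi_hat <- np / n
  ll <- 0
  if (np < n) ll <- ll + (n - np) * log(1 - pi_hat)
  if (np > 0) {
    mu <- mean(pos)
    sigma <- if (np >= 2) sqrt(mean((pos - mu)^2)) else 0
    if (sigma <= 0) sigma <- 1
    ll <- ll + np * log(pi_hat) + sum(stats::dnorm(pos, mu, sigma, log = TRUE))
  }
  ll
}

#' Bimodal likelihood-ratio test for differential expression
#'
#' Each group of (log-normalized) expression values is modeled as a mixture
#' of a point mass at zero and a normal over the positive values, with
#' parameters (pi, mu, sigma) estimated by maximum likelihood; sigma is
#' floored at 1 when a group has fewer than 2 positive values or zero
#' spread. The likelihood-ratio statistic
#' `2 * (L(in) + L(out) - L(pooled))` is referred to the upper tail of the
#' chi-square distribution with 3 degrees of freedom (pi, mu, sigma free
#' per group versus pooled).
#'
#' @param x_in,x_out Non-empty numeric vectors of expression values.
#' @return A list with `lrt_statistic` (>= 0) and `p_value`.
#' @export
bimod_lrt <- function(x_in, x_out) {
  if (length(x_in) < 1 || length(x_out) < 1)
    stop("both groups must be non-empty")
  stat <- 2 * (bimod_loglik(x_in) + bimod_loglik(x_out) -
                 bimod_loglik(c(x_in, x_out)))
  stat <- max(stat, 0)
  list(lrt_statistic = stat,
       p_value = stats::pchisq(stat, df = 3, lower.tail = FALSE))
}

#' Bimodal differential expression between two cell groups
#'
#' Applies [bimod_lrt()] gene by gene between two sets of cells and adjusts
#' p values by Bonferroni over the genes tested.
#'
#' @param nm A [normalized_matrix].
#' @param cells_in,cells_out Character vectors of cell ids.
#' @param genes Optional subset of genes to test (default: all).
#' @return A data frame with `gene`, `lrt_statistic`, `p_value`,
#'   `p_adjusted` and `log_fold_change` (difference of group means of
#'   log-normalized expression), sorted by increasing p then decreasing
#'   statistic.
#' @export
bimod_de <- function(nm, cells_in, cells_out, genes = colnames(nm)) {
  stopifnot(inherits(nm, "normalized_matrix"))
  missing <- setdiff(c(cells_in, cells_out), rownames(nm))
  if (length(missing))
    stop("unknown cell id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  vi <- unclass(nm)[cells_in, genes, drop = FALSE]
  vo <- unclass(nm)[cells_out, genes, drop = FALSE]
  res <- lapply(seq_along(genes), function(j) bimod_lrt(vi[, j], vo[, j]))
  stat <- vapply(res, `[[`, numeric(1), "lrt_statistic")
  p <- vapply(res, `[[`, numeric(1), "p_value")
  out <- data.frame(gene = genes, lrt_statistic = stat, p_value = p,
                    p_adjusted = bonferroni_adjust(p, length(genes)),
                    log_fold_change = colMeans(vi) - colMeans(vo),
                    row.names = NULL)
  out[order(out$p_value, -out$lrt_statistic, out$gene), , drop = FALSE]
}

#' Bonferroni multiple-testing adjustment
#'
#' `p_adj = min(1, p * n_tests)`. `n_tests` defaults to the number of p
#' values supplied (the comparison-level correction) but may be set larger.
#'
#' @param p_values Numeric vector of p values in [0, 1].
#' @param n_tests Number of tests corrected for; at least `length(p_values)`.
#' @return Adjusted p values, same order.
#' @export
bonferroni_adjust <- function(p_values, n_tests = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0, 1]")
  if (n_tests < length(p_values))
    stop("n_tests must be at least the number of p values")
  pmin(1, p_values * n_tests)
}

#' Derive a marker gene signature from a reference cluster
#'
#' Runs the ROC-AUC marker test for the cluster and keeps genes with AUC
#' strictly above `auc_threshold`, sorted by decreasing AUC. An empty
#' result is returned as an explicit empty signature carrying a warning,
#' never silently.
#'
#' @param nm A [normalized_matrix].
#' @param labels A [cluster_assignment].
#' @param cluster_id Reference cluster label.
#' @param auc_threshold Strict AUC cutoff (default 0.65, the scoring
#'   threshold; 0.60 is the reporting threshold).
#' @param name Signature name.
#' @return A [gene_signature]; attribute `empty_signature` is `TRUE` when
#'   no gene passed.
#' @export
derive_signature <- function(nm, labels, cluster_id, auc_threshold = 0.65,
                             name = sprintf("cluster%s_auc%g", cluster_id, auc_threshold)) {
  markers <- roc_auc_marker(nm, labels, cluster_id)
  hits <- markers[markers$auc > auc_threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    warning("empty signature: no gene exceeds AUC ", auc_threshold,
            " for cluster ", cluster_id)
    sig <- gene_signature(character(), numeric(), auc_threshold, name = name)
    attr(sig, "empty_signature") <- TRUE
    return(sig)
  }
  gene_signature(hits$gene, hits$auc, auc_threshold, name = name)
}
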