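#' Transcriptome-fraction signature score
#'
#' The core statistic: for each cell, the summed log-normalized expression
#' of the signature genes divided by the cell's total, giving the fraction
#' of the cell's transcriptome dedicated to producing those genes. Under
#' the default `"lognorm"` denominator the score of the all-genes signature
#' is exactly 1 and scores of disjoint signatures add. The alternative
#' `"scaled_umi"` convention divides by the total scaled UMI in the cell
#' instead.
#'
#' @param nm A [normalized_matrix].
#' @param sig A [gene_list] (or [gene_signature]); must be non-empty and
#'   share at least one gene with the matrix. Signature genes absent from
#'   the matrix contribute 0 and are reported in the `missing_genes`
#'   attribute.
#' @param denominator `"lognorm"` (default) or `"scaled_umi"`.
#' @return A [score_vector] with one score per cell, in [0, 1].
#' @export
score_cells <- function(nm, sig, denominator = c("lognorm", "scaled_umi")) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(sig, "gene_list"))
  denominator <- match.arg(denominator)
  if (!length(sig$genes)) stop("signature is empty")
  present <- intersect(sig$genes, colnames(nm))
  missing <- setdiff(sig$genes, colnames(nm))
  if (!length(present))
    stop("no signature gene found in the matrix; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  v <- unclass(nm)
  num <- rowSums(v[, present, drop = FALSE])
  den <- if (denominator == "lognorm") rowSums(v)
  else {
    # total scaled UMI per cell: counts / total * scale_factor sums to the
    # scale factor for every cell with nonzero depth
    rep(attr(nm, "scale_factor"), nrow(v))
  }
  if (any(den == 0))
    stop("cell(s) with zero total expression: ",
         paste(utils::head(rownames(v)[den == 0], 5), collapse = ", "),
         "; filter before scoring")
  out <- score_vector(pmin(num / den, 1), signature = sig$name,
                      denominator = denominator)
  attr(out, "missing_genes") <- missing
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference `d = (mean_x - mean_y) / sd_pooled` with
#' `sd_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' When the pooled sd is 0 the result is a signed infinity if the means
#' differ (with a warning) and 0 if they coincide.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return Cohen's d; its sign follows `mean(x) - mean(y)`.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  diff <- mean(x) - mean(y)
  if (sp == 0) {
    if (diff == 0) return(0)
    warning("zero pooled sd with unequal means; returning signed infinity")
    return(sign(diff) * Inf)
  }
  diff / sp
}

#' Compare signature scores between two cell groups
#'
#' Two-sided t test (unequal-variance Welch by default; pooled-variance
#' optionally) plus Cohen's d, assembled into a comparison report.
#'
#' @param x,y Numeric vectors of scores (at least 2 cells each), or
#'   [score_vector]s.
#' @param labels Length-2 character vector naming the groups.
#' @param pooled_variance If `TRUE` use the classical equal-variance t
#'   test instead of Welch.
#' @return An object of class `comparison_report`: list with `group`,
#'   `n`, `mean`, `sd_pooled`, `cohens_d`, `t_statistic`, `p_value`.
#' @export
compare_scores <- function(x, y, labels = c("group1", "group2"),
                           pooled_variance = FALSE) {
  if (inherits(x, "score_vector")) x <- x$scores
  if (inherits(y, "score_vector")) y <- y$scores
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 cells")
  d <- suppressWarnings(cohens_d(x, y))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate groups: no within-group spread to test against
    tt <- list(statistic = c(t = if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf),
               p.value = as.numeric(mean(x) == mean(y)))
  } else {
    tt <- stats::t.test(x, y, var.equal = pooled_variance)
  }
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  structure(list(group = labels, n = c(n1, n2),
                 mean = c(mean(x), mean(y)), sd_pooled = sp,
                 cohens_d = d,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison: %s (n=%d, mean %.4f) vs %s (n=%d, mean %.4f)\n",
              x$group[1], x$n[1], x$mean[1], x$group[2], x$n[2], x$mean[2]))
  cat(sprintf("  Cohen's d = %.3f, t = %.3f, p = %.3g\n",
              x$cohens_d, x$t_statistic, x$p_value))
  invisible(x)
}

#' Select the top-scoring cells of a cluster
#'
#' Returns the `n` highest-scoring cells within the given cluster. Ties
#' are broken by cell id, lexicographically, for determinism. If the
#' cluster holds fewer than `n` cells, all of them are returned with a
#' warning and the `short` attribute set.
#'
#' @param scores A [score_vector].
#' @param labels A [cluster_assignment].
#' @param cluster_id Cluster label to select from.
#' @param n Number of cells requested.
#' @return Character vector of cell ids, ordered by decreasing score.
#' @export
select_top_cells <- function(scores, labels, cluster_id, n) {
  stopifnot(inherits(scores, "score_vector"),
            inherits(labels, "cluster_assignment"))
  cells <- names(labels$labels)[labels$labels == cluster_id]
  if (!length(cells)) stop("cluster ", cluster_id, " has no cells")
  s <- scores$scores[cells]
  if (anyNA(s)) stop("scores missing for some cluster cells")
  ord <- cells[order(-s, cells)]
  if (length(ord) < n) {
    warning("cluster ", cluster_id, " has only ", length(ord),
            " cells (requested ", n, "); returning all")
    return(structure(ord, short = TRUE))
  }
  ord[seq_len(n)]
}
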