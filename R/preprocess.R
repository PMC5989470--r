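#' Per-cell quality-control metrics
#'
#' For each cell: total UMIs, number of detected genes (count > 0), and the
#' fractions of counts on mitochondrial (`mt-` prefixed) and ribosomal
#' (`Rps`/`Rpl` prefixed) genes. Prefixes follow mm10 symbol conventions
#' and are case-sensitive but overridable. Zero-count cells get fraction 0
#' by convention and are flagged in the `zero_count` column.
#'
#' @param m A [count_matrix].
#' @param mito_prefix,ribo_prefix Character vectors of gene-symbol prefixes.
#' @return A data frame (one row per cell, in input order) with columns
#'   `cell_id`, `n_umi`, `n_genes`, `pct_mito`, `pct_ribo`, `zero_count`.
#' @export
compute_qc_metrics <- function(m, mito_prefix = "mt-",
                               ribo_prefix = c("Rps", "Rpl")) {
  stopifnot(inherits(m, "count_matrix"), nrow(m) > 0)
  x <- unclass(m)
  n_umi <- rowSums(x)
  n_genes <- rowSums(x > 0)
  starts_any <- function(ids, prefixes)
    Reduce(`|`, lapply(prefixes, function(p) startsWith(ids, p)))
  mito <- starts_any(colnames(x), mito_prefix)
  ribo <- starts_any(colnames(x), ribo_prefix)
  safe_frac <- function(num) ifelse(n_umi > 0, num / pmax(n_umi, 1), 0)
  data.frame(cell_id = rownames(x),
             n_umi = n_umi,
             n_genes = n_genes,
             pct_mito = if (any(mito)) safe_frac(rowSums(x[, mito, drop = FALSE])) else 0,
             pct_ribo = if (any(ribo)) safe_frac(rowSums(x[, ribo, drop = FALSE])) else 0,
             zero_count = n_umi == 0,
             row.names = NULL)
}

#' Quality-control filtering of cells then genes
#'
#' Retains cells with `n_umi >= min_umi`, `n_genes >= min_genes` and
#' `n_umi < max_umi` (boundary semantics: "at least" is inclusive, "less
#' than" is strict, so a cell at exactly `max_umi` is dropped), then
#' retains genes expressed (count > 0) in at least `min_cells_per_gene` of
#' the retained cells. Applied once, cells first then genes, with no
#' iteration; the operation is idempotent.
#'
#' @param m A [count_matrix].
#' @param cfg An [analysis_config] supplying the thresholds.
#' @return The filtered [count_matrix]; attributes `cells_dropped` and
#'   `genes_dropped` record how many were removed.
#' @export
filter_cells_genes <- function(m, cfg = analysis_config()) {
  stopifnot(inherits(m, "count_matrix"))
  qc <- compute_qc_metrics(m)
  keep_cells <- qc$n_umi >= cfg$min_umi & qc$n_genes >= cfg$min_genes &
    qc$n_umi < cfg$max_umi
  if (!any(keep_cells))
    stop("no cells survive QC (min_umi=", cfg$min_umi, ", min_genes=",
         cfg$min_genes, ", max_umi=", cfg$max_umi, ")")
  sub <- unclass(m)[keep_cells, , drop = FALSE]
  keep_genes <- colSums(sub > 0) >= cfg$min_cells_per_gene
  if (!any(keep_genes))
    stop("no genes survive QC (min_cells_per_gene=", cfg$min_cells_per_gene,
         " over ", sum(keep_cells), " retained cells)")
  out <- count_matrix(sub[, keep_genes, drop = FALSE],
                      sample_label = attr(m, "sample_label"))
  attr(out, "cells_dropped") <- sum(!keep_cells)
  attr(out, "genes_dropped") <- sum(!keep_genes)
  out
}

#' Depth-normalize and log-transform a count matrix
#'
#' Computes `log(count / cell_total * scale_factor + 1)` per entry (natural
#' log), the standard per-cell depth scaling. The result is invariant to
#' rescaling any cell's counts by a constant.
#'
#' @param m A [count_matrix]; every cell must have at least one count
#'   (filter first).
#' @param scale_factor Positive scale factor, default 10,000.
#' @return A [normalized_matrix].
#' @export
normalize_log_scaled <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "count_matrix"), scale_factor > 0)
  x <- unclass(m)
  tot <- rowSums(x)
  if (any(tot == 0))
    stop("zero-count cell(s) present: ",
         paste(utils::head(rownames(x)[tot == 0], 5), collapse = ", "),
         "; run filter_cells_genes() first")
  v <- log1p(x / tot * scale_factor)
  normalized_matrix(v, scale_factor = scale_factor,
                    provenance = list(sample_label = attr(m, "sample_label"),
                                      n_cells = nrow(x), n_genes = ncol(x)))
}

#' Select highly variable genes
#'
#' Per gene, the mean and the dispersion (variance / mean, sample variance
#' with n - 1 denominator) are computed on the log-normalized values across
#' cells; genes exceeding both cutoffs (strictly) are kept. Genes with zero
#' mean are excluded.
#'
#' @param nm A [normalized_matrix] with at least 2 cells.
#' @param cfg An [analysis_config]; uses `var_mean_cutoff` (default 0.14)
#'   and `var_dispersion_cutoff` (default 0.4).
#' @return An object of class `variable_gene_set`: list with `genes` and
#'   the per-gene `stats` data frame (mean, dispersion) used for selection.
#' @export
select_variable_genes <- function(nm, cfg = analysis_config()) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (nrow(nm) < 2) stop("variance needs at least 2 cells")
  v <- unclass(nm)
  n <- nrow(v)
  mu <- colMeans(v)
  vr <- (colSums(v^2) - n * mu^2) / (n - 1)
  vr <- pmax(vr, 0)  # guard tiny negative values from cancellation
  disp <- ifelse(mu > 0, vr / mu, NA_real_)
  keep <- !is.na(disp) & mu > cfg$var_mean_cutoff &
    disp > cfg$var_dispersion_cutoff
  structure(list(genes = colnames(v)[keep],
                 stats = data.frame(gene = colnames(v), mean = mu,
                                    dispersion = disp, selected = keep,
                                    row.names = NULL)),
            class = "variable_gene_set")
}

#' @export
print.variable_gene_set <- function(x, ...) {
  cat(sprintf("variable_gene_set: %d of %d genes selected\n",
              length(x$genes), nrow(x$stats)))
  invisible(x)
}
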