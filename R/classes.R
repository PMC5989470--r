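#' Construct a UMI count matrix
#'
#' The canonical container for UMI-collapsed digital gene expression (DGE)
#' data: a cells x genes matrix of non-negative integer counts with unique
#' cell barcodes as row names and unique gene symbols as column names.
#'
#' @param counts Numeric matrix, cells in rows and genes in columns. All
#'   entries must be non-negative integers (integer-valued doubles accepted).
#' @param cell_ids Character vector of unique cell barcodes; defaults to the
#'   row names of `counts`.
#' @param gene_ids Character vector of unique gene symbols; defaults to the
#'   column names of `counts`.
#' @param sample_label Free-text label for the sample or condition.
#' @return An object of class `count_matrix`: the integer matrix with
#'   dimnames set and a `sample_label` attribute.
#' @examples
#' m <- count_matrix(matrix(0:5, 2, 3,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))))
#' n_cells(m)
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), sample_label = "") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("count_matrix requires cell and gene identifiers")
  if (length(cell_ids) != nrow(counts))
    stop("length(cell_ids) must equal nrow(counts)")
  if (length(gene_ids) != ncol(counts))
    stop("length(gene_ids) must equal ncol(counts)")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup))
    stop("duplicate cell barcodes: ", paste(dup, collapse = ", "))
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  if (anyNA(counts) || !is.numeric(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral (UMI counts)")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(counts, sample_label = sample_label, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes", nrow(x), ncol(x)))
  lab <- attr(x, "sample_label")
  if (nzchar(lab)) cat(sprintf(" [%s]", lab))
  cat(sprintf("; total UMIs %s\n", format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Number of cells / genes in a matrix container
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x)

#' Construct a gene list
#'
#' An ordered, duplicate-free list of gene symbols (a signature, pathway
#' set, or transcription-factor catalog). Gene identity is the symbol
#' string, case-sensitive.
#'
#' @param genes Character vector of gene symbols.
#' @param name Name of the list.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(genes, name = "gene_list") {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  structure(list(name = name, genes = genes), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d genes\n", x$name, length(x$genes)))
  show <- utils::head(x$genes, 6)
  cat(" ", paste(show, collapse = ", "),
      if (length(x$genes) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$genes)

#' Construct a normalized expression matrix
#'
#' Holds per-cell depth-scaled, log-transformed expression:
#' `log(count / cell_total * scale_factor + 1)` (natural log). Produced by
#' [normalize_log_scaled()]; constructed directly only in tests.
#'
#' @param values Cells x genes non-negative real matrix with dimnames.
#' @param scale_factor Scale factor used during normalization.
#' @param provenance Optional list describing the source matrix and filters.
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, scale_factor, provenance = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry cell and gene identifiers as dimnames")
  if (any(!is.finite(values)))
    stop("normalized values must be finite")
  if (any(values < 0))
    stop("normalized values must be non-negative")
  structure(values, scale_factor = scale_factor, provenance = provenance,
            class = c("normalized_matrix", "matrix", "array"))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (scale factor %g, natural log)\n",
              nrow(x), ncol(x), attr(x, "scale_factor")))
  invisible(x)
}

#' Construct a cluster assignment
#'
#' Per-cell integer cluster labels, contiguous from 0, as produced by SNN
#' modularity clustering.
#'
#' @param labels Integer vector of labels, named by cell id.
#' @param resolution Resolution parameter used.
#' @param seed RNG seed used.
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, resolution = NA_real_, seed = NA_integer_) {
  if (is.null(names(labels))) stop("labels must be named by cell id")
  ids <- names(labels)
  labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!identical(u, seq_along(u) - 1L))
    stop("labels must be contiguous integers starting at 0")
  structure(list(labels = stats::setNames(labels, ids),
                 resolution = resolution, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("cluster_assignment: %d cells in %d clusters (resolution %s)\n",
              length(x$labels), length(tab), format(x$resolution)))
  print(tab)
  invisible(x)
}

#' Construct a gene signature
#'
#' A ranked marker gene list with per-gene ROC AUC, as derived from a
#' reference cluster by [derive_signature()].
#'
#' @param genes Character vector of gene symbols, sorted by decreasing AUC.
#' @param auc Numeric vector of AUC values aligned with `genes`.
#' @param threshold The AUC threshold that produced the signature.
#' @param name Signature name.
#' @return An object of class `gene_signature` (also a `gene_list`).
#' @export
gene_signature <- function(genes, auc, threshold, name = "signature") {
  gl <- gene_list(genes, name = name)
  if (length(auc) != length(gl$genes))
    stop("auc must align with genes")
  structure(list(name = name, genes = gl$genes,
                 auc = stats::setNames(as.numeric(auc), gl$genes),
                 threshold = threshold),
            class = c("gene_signature", "gene_list"))
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes with AUC > %g\n",
              x$name, length(x$genes), x$threshold))
  if (length(x$genes)) {
    top <- utils::head(x$genes, 5)
    cat("  top: ", paste(sprintf("%s (%.3f)", top, x$auc[top]), collapse = ", "), "\n")
  }
  if (isTRUE(attr(x, "empty_signature")))
    cat("  (empty: no gene exceeded the threshold)\n")
  invisible(x)
}

#' Construct a per-cell score vector
#'
#' Fraction of each cell's transcriptome dedicated to a gene list, in [0, 1].
#'
#' @param scores Numeric vector named by cell id.
#' @param signature Signature name.
#' @param denominator Denominator convention tag: `"lognorm"` (sum of
#'   log-normalized values, the default convention) or `"scaled_umi"`.
#' @return An object of class `score_vector`.
#' @export
score_vector <- function(scores, signature, denominator = "lognorm") {
  if (is.null(names(scores))) stop("scores must be named by cell id")
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  structure(list(scores = scores, signature = signature,
                 denominator = denominator),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector '%s' (%s denominator): %d cells, mean %.4f\n",
              x$signature, x$denominator, length(x$scores), mean(x$scores)))
  invisible(x)
}
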