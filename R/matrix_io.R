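#' Read a dense digital gene expression (DGE) table
#'
#' Reads a tab-separated DGE table into a [count_matrix]. The common DGE
#' dialect stores genes in rows and cells in columns with the top-left
#' header cell `GENE`; that is the default orientation. The returned matrix
#' is always cells x genes regardless of the on-disk orientation.
#'
#' @param path Path to a TSV file. First row and first column are axis
#'   labels; the body must parse as non-negative integers.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`,
#'   describing the file layout.
#' @param sample_label Optional sample label attached to the result.
#' @return A [count_matrix] (cells x genes).
#' @export
read_dense_dge <- function(path, orientation = c("genes_by_cells", "cells_by_genes"),
                           sample_label = "") {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("DGE table needs at least one label column and one data column")
  row_ids <- as.character(tab[[1]])
  body <- tab[, -1, drop = FALSE]
  col_ids <- colnames(body)
  vals <- as.matrix(body)
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) , arr.ind = TRUE)
    if (nrow(bad) == 0) {
      vals <- matrix(as.numeric(vals), nrow(vals), dimnames = dimnames(vals))
    } else {
      stop(sprintf("non-numeric entry at row %d ('%s'), column %d ('%s')",
                   bad[1, 1], row_ids[bad[1, 1]], bad[1, 2], col_ids[bad[1, 2]]))
    }
  }
  nonint <- which(vals != round(vals), arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop(sprintf("non-integer count %g at row %d ('%s'), column %d ('%s')",
                 vals[nonint[1, , drop = FALSE]], nonint[1, 1], row_ids[nonint[1, 1]],
                 nonint[1, 2], col_ids[nonint[1, 2]]))
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at row %d ('%s'), column %d ('%s')",
                 neg[1, 1], row_ids[neg[1, 1]], neg[1, 2], col_ids[neg[1, 2]]))
  rownames(vals) <- row_ids
  if (orientation == "genes_by_cells") vals <- t(vals)
  count_matrix(vals, sample_label = sample_label)
}

#' Write a dense DGE table
#'
#' Writes a [count_matrix] as tab-separated text, genes in rows and cells in
#' columns, with the top-left header cell `GENE`.
#'
#' @param m A [count_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dense_dge <- function(m, path) {
  tab <- t(unclass(m))
  out <- data.frame(GENE = rownames(tab), tab, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse coordinate-triplet count matrix
#'
#' Reads a MatrixMarket-style coordinate file with 1-based `gene cell count`
#' triplets plus sidecar files of barcodes and gene symbols (one identifier
#' per line), and densifies to a [count_matrix]. Unlisted coordinates are
#' zero.
#'
#' @param matrix_path Coordinate file. Lines beginning with `%` are
#'   comments; the first non-comment line is the header
#'   `n_genes n_cells n_entries`.
#' @param barcodes_path One cell barcode per line.
#' @param genes_path One gene symbol per line.
#' @param sample_label Optional sample label.
#' @return A [count_matrix] (cells x genes).
#' @export
read_sparse_triplet <- function(matrix_path, barcodes_path, genes_path,
                                sample_label = "") {
  lines <- readLines(matrix_path)
  lines <- lines[!startsWith(lines, "%")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("sparse matrix file has no header line")
  hdr <- scan(text = lines[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 3) stop("sparse header must be 'n_genes n_cells n_entries'")
  ng <- hdr[1]; nc <- hdr[2]; ne <- hdr[3]
  genes <- trimws(readLines(genes_path)); genes <- genes[nzchar(genes)]
  cells <- trimws(readLines(barcodes_path)); cells <- cells[nzchar(cells)]
  if (length(genes) != ng)
    stop(sprintf("header declares %d genes but sidecar lists %d", ng, length(genes)))
  if (length(cells) != nc)
    stop(sprintf("header declares %d cells but sidecar lists %d", nc, length(cells)))
  body <- lines[-1]
  if (length(body) != ne)
    stop(sprintf("header declares %d entries but file has %d", ne, length(body)))
  m <- matrix(0, nrow = nc, ncol = ng, dimnames = list(cells, genes))
  if (length(body)) {
    trip <- matrix(scan(text = body, what = numeric(), quiet = TRUE),
                   ncol = 3, byrow = TRUE)
    if (any(trip[, 1] < 1 | trip[, 1] > ng | trip[, 2] < 1 | trip[, 2] > nc))
      stop("triplet index out of declared range")
    m[cbind(trip[, 2], trip[, 1])] <- trip[, 3]
  }
  count_matrix(m, sample_label = sample_label)
}

#' Write a sparse coordinate-triplet count matrix
#'
#' Inverse of [read_sparse_triplet()]: writes the non-zero entries as
#' 1-based `gene cell count` triplets with a MatrixMarket-style header and
#' barcode/gene sidecar files.
#'
#' @param m A [count_matrix].
#' @param matrix_path,barcodes_path,genes_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_sparse_triplet <- function(m, matrix_path, barcodes_path, genes_path) {
  nz <- which(unclass(m) != 0, arr.ind = TRUE)
  hdr <- sprintf("%d %d %d", ncol(m), nrow(m), nrow(nz))
  body <- if (nrow(nz)) sprintf("%d %d %d", nz[, 2], nz[, 1], m[nz]) else character()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", hdr, body),
             matrix_path)
  writeLines(rownames(m), barcodes_path)
  writeLines(colnames(m), genes_path)
  invisible(matrix_path)
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; surrounding whitespace is stripped and blank
#' lines ignored. Order is preserved; duplicates are an error.
#'
#' @param path Path to the file.
#' @param name Name for the list; defaults to the file name without
#'   extension.
#' @param header If `TRUE`, the first non-blank line is discarded.
#' @return A [gene_list].
#' @export
read_gene_list <- function(path, name = NULL,
                           header = FALSE) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) stop("gene list file is empty: ", path)
  gene_list(lines, name = name)
}

#' Write a tabular result as TSV
#'
#' All tabular pipeline outputs (marker tables, score tables, reports) are
#' written as tab-separated text with a header row.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
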