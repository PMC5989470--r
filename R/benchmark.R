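#' Run the full cell-type fidelity benchmark
#'
#' Orchestrates the whole pipeline: the reference dataset is QC-filtered,
#' normalized, clustered, and a marker signature is derived from its
#' reference cell-type cluster at the scoring AUC threshold; the query
#' conditions are merged over the shared gene universe, QC-filtered,
#' normalized, reduced and clustered; every query cell is scored for the
#' reference signature; and per-cluster comparison reports are assembled
#' against the remaining query cells and against the reference population
#' itself. Fully deterministic given `cfg$rng_seed` (per-stage seeds are
#' fanned out with [derive_seed()]).
#'
#' The reference cluster is either given explicitly (`ref_cluster`) or
#' picked automatically as the cluster with the highest mean
#' transcriptome-fraction score of `ref_markers` (e.g. a canonical marker
#' list for the cell type of interest).
#'
#' @param reference A [count_matrix] of the in vivo reference dataset.
#' @param query_conditions Named list of [count_matrix] objects, one per in
#'   vitro condition; names are the condition tags.
#' @param cfg An [analysis_config] applied to the query analysis.
#' @param ref_cfg Configuration for the reference analysis (defaults to
#'   `cfg`; the two runs may legitimately use different settings).
#' @param ref_markers A [gene_list] used to locate the reference cluster
#'   automatically; ignored when `ref_cluster` is given.
#' @param ref_cluster Optional explicit reference cluster label.
#' @return An object of class `benchmark_report`: list with the derived
#'   `signature`, per-cluster table `cluster_scores` (mean score, Cohen's d
#'   and Welch p versus all other query cells and versus the reference
#'   population), `condition_fractions`, the per-cell `scores` and
#'   `labels`, the reference population's own scores (`reference_scores`),
#'   and a `provenance` block (configs, seeds, gene-universe bookkeeping).
#' @export
run_benchmark <- function(reference, query_conditions, cfg = analysis_config(),
                          ref_cfg = cfg, ref_markers = NULL,
                          ref_cluster = NULL) {
  stopifnot(inherits(reference, "count_matrix"), length(query_conditions) >= 1)
  if (is.null(names(query_conditions)) || any(!nzchar(names(query_conditions))))
    stop("query_conditions must be a named list (condition tags)")

  # ---- harmonize gene universes by symbol intersection
  universes <- c(list(colnames(reference)),
                 lapply(query_conditions, colnames))
  shared <- Reduce(intersect, universes)
  if (!length(shared)) stop("reference and queries share no genes")
  dropped <- sum(vapply(universes, function(u) length(setdiff(u, shared)),
                        numeric(1)))
  reference <- count_matrix(unclass(reference)[, shared, drop = FALSE],
                            sample_label = attr(reference, "sample_label"))
  query_conditions <- lapply(query_conditions, function(q)
    count_matrix(unclass(q)[, shared, drop = FALSE],
                 sample_label = attr(q, "sample_label")))

  # ---- reference arm: cluster and derive the cell-type signature
  ref_f <- filter_cells_genes(reference, ref_cfg)
  ref_nm <- normalize_log_scaled(ref_f, ref_cfg$scale_factor)
  ref_var <- select_variable_genes(ref_nm, ref_cfg)
  if (!length(ref_var$genes)) stop("no variable genes in the reference")
  ref_pca <- run_pca(ref_nm, ref_var, n_pcs = min(ref_cfg$n_pcs, nrow(ref_nm) - 1),
                     clip = ref_cfg$pca_clip)
  ref_snn <- build_snn_graph(ref_pca, k = min(ref_cfg$snn_k, nrow(ref_nm) - 1),
                             prune = ref_cfg$snn_prune)
  ref_lab <- cluster_graph(ref_snn, resolution = ref_cfg$resolution,
                           seed = derive_seed(ref_cfg$rng_seed, "cluster_reference"))
  if (is.null(ref_cluster)) {
    if (is.null(ref_markers))
      stop("supply ref_cluster or ref_markers to locate the reference cell type")
    marker_scores <- score_cells(ref_nm, ref_markers,
                                 denominator = ref_cfg$score_denominator)
    cl_means <- tapply(marker_scores$scores[names(ref_lab$labels)],
                       ref_lab$labels, mean)
    ref_cluster <- as.integer(names(cl_means)[which.max(cl_means)])
  }
  signature <- derive_signature(ref_nm, ref_lab, ref_cluster,
                                auc_threshold = ref_cfg$marker_auc_score,
                                name = "reference_signature")
  if (isTRUE(attr(signature, "empty_signature")))
    stop("reference signature is empty at AUC > ", ref_cfg$marker_auc_score,
         " for cluster ", ref_cluster)
  ref_scores <- score_cells(ref_nm, signature,
                            denominator = ref_cfg$score_denominator)
  ref_pop <- ref_scores$scores[names(ref_lab$labels)[ref_lab$labels == ref_cluster]]

  # ---- query arm: merge conditions, cluster, score
  merged <- do.call(rbind, lapply(names(query_conditions), function(cn) {
    q <- unclass(query_conditions[[cn]])
    rownames(q) <- paste(cn, rownames(q), sep = ":")
    q
  }))
  condition_of_cell <- sub(":.*$", "", rownames(merged))
  qm <- count_matrix(merged, sample_label = "merged_query")
  qf <- filter_cells_genes(qm, cfg)
  condition_of_cell <- stats::setNames(sub(":.*$", "", rownames(qf)), rownames(qf))
  q_nm <- normalize_log_scaled(qf, cfg$scale_factor)
  q_var <- select_variable_genes(q_nm, cfg)
  if (!length(q_var$genes)) stop("no variable genes in the merged query")
  q_pca <- run_pca(q_nm, q_var, n_pcs = min(cfg$n_pcs, nrow(q_nm) - 1),
                   clip = cfg$pca_clip)
  q_snn <- build_snn_graph(q_pca, k = min(cfg$snn_k, nrow(q_nm) - 1),
                           prune = cfg$snn_prune)
  q_lab <- cluster_graph(q_snn, resolution = cfg$resolution,
                         seed = derive_seed(cfg$rng_seed, "cluster_query"))
  q_scores <- score_cells(q_nm, signature, denominator = cfg$score_denominator)

  # ---- per-cluster comparisons
  clusters <- sort(unique(q_lab$labels))
  rows <- lapply(clusters, function(cl) {
    cells <- names(q_lab$labels)[q_lab$labels == cl]
    others <- setdiff(names(q_lab$labels), cells)
    sc <- q_scores$scores[cells]
    row <- data.frame(cluster = cl, n_cells = length(cells),
                      mean_score = mean(sc),
                      d_vs_rest = NA_real_, p_vs_rest = NA_real_,
                      d_vs_reference = NA_real_, p_vs_reference = NA_real_)
    if (length(cells) >= 2 && length(others) >= 2) {
      cr <- compare_scores(sc, q_scores$scores[others])
      row$d_vs_rest <- cr$cohens_d; row$p_vs_rest <- cr$p_value
    }
    if (length(cells) >= 2 && length(ref_pop) >= 2) {
      cr <- compare_scores(ref_pop, sc)
      row$d_vs_reference <- cr$cohens_d; row$p_vs_reference <- cr$p_value
    }
    row
  })
  cluster_scores <- do.call(rbind, rows)

  structure(list(signature = signature,
                 cluster_scores = cluster_scores,
                 condition_fractions =
                   condition_cluster_fractions(q_lab, condition_of_cell),
                 scores = q_scores, labels = q_lab,
                 reference_scores = ref_scores,
                 reference_cluster = ref_cluster,
                 reference_labels = ref_lab,
                 provenance = list(cfg = unclass(cfg), ref_cfg = unclass(ref_cfg),
                                   rng_seed = cfg$rng_seed,
                                   shared_genes = length(shared),
                                   genes_dropped_in_harmonization = dropped)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d-gene signature (cluster %d of reference), %d query clusters\n",
              length(x$signature$genes), x$reference_cluster,
              nrow(x$cluster_scores)))
  print(x$cluster_scores, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Cluster frequencies within each condition
#'
#' Tabulates, for every condition, the fraction of its cells assigned to
#' each cluster. Rows (conditions) sum to 1.
#'
#' @param labels A [cluster_assignment].
#' @param condition_of_cell Character vector of condition tags named by
#'   cell id, covering every labeled cell.
#' @return A conditions x clusters matrix of fractions.
#' @export
condition_cluster_fractions <- function(labels, condition_of_cell) {
  stopifnot(inherits(labels, "cluster_assignment"))
  cond <- condition_of_cell[names(labels$labels)]
  if (anyNA(cond)) stop("every cell needs a condition tag")
  tab <- table(cond, labels$labels)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  m <- matrix(as.numeric(frac), nrow(frac), ncol(frac),
              dimnames = list(rownames(frac), colnames(frac)))
  m
}

#' Row-normalized z-score matrix for heatmap display
#'
#' For the selected genes and cells, each gene is z-scored across the
#' selected cells ((x - mean) / sd, n - 1 denominator) and clipped to
#' `+/- clip` (default 2.5, the display range). Zero-variance genes get
#' all-zero rows and are flagged. Gene rows are ordered by hierarchical
#' clustering (average linkage, Euclidean distance); cells are ordered by
#' `cell_group` then decreasing `cell_score` when supplied.
#'
#' @param nm A [normalized_matrix].
#' @param cells,genes Character vectors selecting the submatrix.
#' @param clip Symmetric clip bound (default 2.5).
#' @param cell_group Optional grouping vector named by cell id.
#' @param cell_score Optional ordering score named by cell id.
#' @return An object of class `heatmap_matrix`: the genes x cells clipped
#'   z-score matrix with attributes `flat_genes` (zero-variance genes) and
#'   `clip`.
#' @export
heatmap_zscore_matrix <- function(nm, cells, genes, clip = 2.5,
                                  cell_group = NULL, cell_score = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"), clip > 0)
  missing <- setdiff(cells, rownames(nm))
  if (length(missing)) stop("unknown cell(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  missing <- setdiff(genes, colnames(nm))
  if (length(missing)) stop("unknown gene(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  v <- unclass(nm)[cells, genes, drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  z <- sweep(v, 2, mu, "-")
  ok <- sdv > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
  z[, !ok] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  zg <- t(z)  # genes x cells
  if (nrow(zg) > 2) {
    hc <- stats::hclust(stats::dist(zg), method = "average")
    zg <- zg[hc$order, , drop = FALSE]
  }
  if (!is.null(cell_group) || !is.null(cell_score)) {
    grp <- if (is.null(cell_group)) rep("", length(cells)) else cell_group[cells]
    sco <- if (is.null(cell_score)) rep(0, length(cells)) else cell_score[cells]
    zg <- zg[, order(grp, -sco), drop = FALSE]
  }
  structure(zg, flat_genes = genes[!ok], clip = clip,
            class = c("heatmap_matrix", "matrix", "array"))
}

#' Restrict a signature to transcription factors
#'
#' Intersects a derived [gene_signature] with a transcription-factor
#' catalog, preserving the signature's order and per-gene AUCs. An empty
#' intersection yields an explicit empty signature with a warning.
#'
#' @param sig A [gene_signature].
#' @param tf_catalog A non-empty [gene_list] of transcription factors.
#' @return A [gene_signature] restricted to the catalog.
#' @export
tf_filter <- function(sig, tf_catalog) {
  stopifnot(inherits(sig, "gene_signature"), inherits(tf_catalog, "gene_list"))
  if (!length(tf_catalog$genes)) stop("transcription-factor catalog is empty")
  keep <- sig$genes[sig$genes %in% tf_catalog$genes]
  if (!length(keep)) {
    warning("no signature gene found in the transcription-factor catalog")
    out <- gene_signature(character(), numeric(), sig$threshold,
                          name = paste0(sig$name, "_tf"))
    attr(out, "empty_signature") <- TRUE
    return(out)
  }
  gene_signature(keep, sig$auc[keep], sig$threshold,
                 name = paste0(sig$name, "_tf"))
}

#' Run the synthetic fidelity-dial experiment
#'
#' The package's reference parameter-recovery scenario. A synthetic in vivo
#' dataset is generated from four expression programs, one of which plays
#' the reference cell type; synthetic in vitro conditions replace that
#' program with a degraded analog interpolated toward it by a fidelity
#' delta. All conditions are merged and benchmarked in one pipeline run
#' ([run_benchmark()]), and for every condition the best per-cluster mean
#' transcriptome-fraction score of the reference signature is reported.
#' Higher-fidelity conditions should score higher (monotone recovery).
#'
#' @param deltas Fidelity values in [0, 1], one synthetic condition each.
#' @param n_cells Cells per generated dataset.
#' @param seed Global seed; per-dataset seeds are fanned out with
#'   [derive_seed()].
#' @param cfg An [analysis_config]; the default uses resolution 0.5, suited
#'   to the coarse population structure of the synthetic benchmark.
#' @param min_cluster_fraction A cluster counts as a candidate population
#'   for a condition only when it holds at least this fraction of the
#'   condition's cells (and never fewer than 5 cells). The floor keeps a
#'   handful of extreme cells from being read as a population.
#' @return A list with `per_condition` (data frame: delta, best cluster,
#'   mean score, n cells), the full `report`, and `reference_mean` (mean
#'   score of the reference population on its own signature).
#' @export
run_fidelity_experiment <- function(deltas = c(0, 0.25, 0.5, 0.75, 1),
                                    n_cells = 600, seed = 1L,
                                    cfg = analysis_config(resolution = 0.5,
                                                          rng_seed = seed),
                                    min_cluster_fraction = 0.05) {
  make_spec <- function(props, fid, s)
    synthetic_benchmark_spec(n_programs = 4, proportions = props,
                             n_cells = n_cells, fidelity = fid,
                             reference_program = if (is.null(fid)) NULL else 1L,
                             rng_seed = s)
  ref <- generate_counts(make_spec(c(1, 0, 1, 1) / 3, NULL,
                                   derive_seed(seed, "fidelity_reference")))
  ref_markers <- gene_list(ref$ground_truth$markers[["program1"]],
                           name = "reference_markers")
  queries <- lapply(seq_along(deltas), function(i) {
    d <- deltas[i]
    sim <- generate_counts(make_spec(c(0, 1, 1, 1) / 3, c(0, d, 0, 0),
                                     derive_seed(seed, sprintf("fidelity_query_%d", i))))
    sim$counts
  })
  names(queries) <- sprintf("delta%03d", round(deltas * 100))
  rep <- run_benchmark(ref$counts, queries, cfg = cfg,
                       ref_markers = ref_markers)
  cond <- sub(":.*$", "", names(rep$labels$labels))
  per_condition <- do.call(rbind, lapply(seq_along(deltas), function(i) {
    cn <- names(queries)[i]
    cells <- names(rep$labels$labels)[cond == cn]
    labs <- rep$labels$labels[cells]
    means <- tapply(rep$scores$scores[cells], labs, mean)
    sizes <- table(labs)
    floor_n <- max(5, ceiling(min_cluster_fraction * length(cells)))
    means <- means[sizes[names(means)] >= floor_n]
    best <- names(means)[which.max(means)]
    data.frame(delta = deltas[i], condition = cn,
               best_cluster = as.integer(best),
               best_mean_score = unname(means[best]),
               n_cells = as.integer(sizes[best]))
  }))
  ref_cells <- names(rep$reference_labels$labels)[
    rep$reference_labels$labels == rep$reference_cluster]
  list(per_condition = per_condition, report = rep,
       reference_mean = mean(rep$reference_scores$scores[ref_cells]))
}
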