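#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline with the study defaults:
#' cells with at least `min_umi` (1000) UMIs, at least `min_genes` (400)
#' detected genes and fewer than `max_umi` (8000) UMIs are retained; genes
#' expressed in at least `min_cells_per_gene` (5) retained cells are kept;
#' normalization uses `scale_factor` 10,000 and the natural log; variable
#' genes need mean normalized expression above `var_mean_cutoff` (0.14) and
#' variance/mean dispersion above `var_dispersion_cutoff` (0.4); clustering
#' uses the first `n_pcs` (12) principal components, a shared-nearest-
#' neighbor graph with `snn_k` (20) neighbors pruned at Jaccard weight
#' `snn_prune` (1/15), and Louvain modularity at `resolution` 1.35; marker
#' genes are reported at ROC AUC above `marker_auc_report` (0.60) and
#' scored at above `marker_auc_score` (0.65).
#'
#' @param scale_factor Positive depth-normalization scale factor.
#' @param min_umi Minimum UMIs per retained cell (inclusive).
#' @param min_genes Minimum detected genes per retained cell (inclusive).
#' @param max_umi Upper UMI bound per retained cell (exclusive).
#' @param min_cells_per_gene Minimum retained cells expressing a kept gene.
#' @param var_mean_cutoff Mean normalized expression cutoff (strict).
#' @param var_dispersion_cutoff Variance/mean dispersion cutoff (strict).
#' @param n_pcs Number of principal components used downstream.
#' @param snn_k Neighbors per cell in the kNN graph (self included).
#' @param snn_prune Jaccard weight at or below which SNN edges are dropped.
#' @param resolution Louvain modularity resolution.
#' @param marker_auc_report AUC threshold for reporting markers.
#' @param marker_auc_score AUC threshold for scoring signatures.
#' @param pca_clip Z-scores are clipped to this magnitude before PCA.
#' @param score_denominator `"lognorm"` or `"scaled_umi"`; see
#'   [score_cells()].
#' @param rng_seed Integer seed fanned out to every stochastic stage.
#' @return An object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(scale_factor = 10000,
                            min_umi = 1000,
                            min_genes = 400,
                            max_umi = 8000,
                            min_cells_per_gene = 5,
                            var_mean_cutoff = 0.14,
                            var_dispersion_cutoff = 0.4,
                            n_pcs = 12,
                            snn_k = 20,
                            snn_prune = 1 / 15,
                            resolution = 1.35,
                            marker_auc_report = 0.60,
                            marker_auc_score = 0.65,
                            pca_clip = 10,
                            score_denominator = "lognorm",
                            rng_seed = 1L) {
  cfg <- list(scale_factor = scale_factor, min_umi = min_umi,
              min_genes = min_genes, max_umi = max_umi,
              min_cells_per_gene = min_cells_per_gene,
              var_mean_cutoff = var_mean_cutoff,
              var_dispersion_cutoff = var_dispersion_cutoff,
              n_pcs = n_pcs, snn_k = snn_k, snn_prune = snn_prune,
              resolution = resolution,
              marker_auc_report = marker_auc_report,
              marker_auc_score = marker_auc_score,
              pca_clip = pca_clip,
              score_denominator = score_denominator,
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, constraint) {
    if (!ok) stop(sprintf("config key '%s': %s", key, constraint), call. = FALSE)
  }
  chk(cfg$scale_factor > 0, "scale_factor", "must be positive")
  chk(cfg$min_umi >= 0, "min_umi", "must be non-negative")
  chk(cfg$min_genes >= 0, "min_genes", "must be non-negative")
  chk(cfg$min_umi < cfg$max_umi, "max_umi", "must exceed min_umi")
  chk(cfg$min_cells_per_gene >= 0, "min_cells_per_gene", "must be non-negative")
  chk(cfg$n_pcs >= 1, "n_pcs", "must be at least 1")
  chk(cfg$snn_k >= 1, "snn_k", "must be at least 1")
  chk(cfg$snn_prune >= 0 && cfg$snn_prune < 1, "snn_prune", "must lie in [0, 1)")
  chk(cfg$resolution > 0, "resolution", "must be positive")
  chk(cfg$marker_auc_report >= 0 && cfg$marker_auc_report <= 1,
      "marker_auc_report", "must lie in [0, 1]")
  chk(cfg$marker_auc_score >= 0 && cfg$marker_auc_score <= 1,
      "marker_auc_score", "must lie in [0, 1]")
  chk(cfg$pca_clip > 0, "pca_clip", "must be positive")
  chk(cfg$score_denominator %in% c("lognorm", "scaled_umi"),
      "score_denominator", "must be 'lognorm' or 'scaled_umi'")
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take the documented defaults; unknown keys are
#' rejected. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML key-value file.
#' @return An [analysis_config].
#' @export
load_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write a configuration to a YAML file
#'
#' @param cfg An [analysis_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Derive a stage-specific RNG seed from the global seed
#'
#' One global seed fans out to per-stage seeds by a stable string hash of
#' the stage name, so individual stages can be re-run independently yet
#' deterministically. The result is always in `[0, 2^31 - 1)`.
#'
#' @param seed Global integer seed.
#' @param stage Stage name, e.g. `"cluster"` or `"simulate"`.
#' @return A non-negative integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Write a run manifest
#'
#' Records everything needed to re-run a pipeline stage bit-identically:
#' the configuration snapshot, global seed, MD5 digests of the input files,
#' the package version and a timestamp. Written as JSON.
#'
#' @param path Output path for the manifest JSON.
#' @param subcommand Name of the stage or subcommand run.
#' @param cfg The [analysis_config] used.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param outputs Character vector of output file paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, subcommand, cfg, inputs = character(),
                           outputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(subcommand = subcommand,
                   config = unclass(cfg),
                   rng_seed = cfg$rng_seed,
                   input_digests = digests,
                   outputs = as.list(outputs),
                   package_version = as.character(utils::packageVersion("scfidelity")),
                   timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
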