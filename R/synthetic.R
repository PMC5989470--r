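#' Define an expression program for the synthetic simulator
#'
#' A cell program is a set of per-gene relative expression propensities plus
#' a designated set of marker genes that are upweighted `marker_fold`-fold
#' relative to the background. Weights are normalized to sum to 1 before
#' sampling.
#'
#' @param name Program name.
#' @param gene_weights Non-negative numeric vector named by gene; relative
#'   propensities before marker upweighting.
#' @param marker_genes Character vector of genes (a subset of
#'   `names(gene_weights)`) upweighted by `marker_fold`.
#' @param marker_fold Fold upweighting applied to markers; must be >= 1.
#' @return An object of class `cell_program`.
#' @export
cell_program <- function(name, gene_weights, marker_genes = character(),
                         marker_fold = 1) {
  if (is.null(names(gene_weights))) stop("gene_weights must be named by gene")
  if (any(gene_weights < 0)) stop("gene_weights must be non-negative")
  if (marker_fold < 1) stop("marker_fold must be >= 1")
  missing <- setdiff(marker_genes, names(gene_weights))
  if (length(missing))
    stop("marker genes absent from the gene axis: ", paste(missing, collapse = ", "))
  w <- gene_weights
  w[marker_genes] <- w[marker_genes] * marker_fold
  if (sum(w) <= 0) stop("program '", name, "' has zero total weight")
  w <- w / sum(w)
  structure(list(name = name, gene_weights = w, marker_genes = marker_genes),
            class = "cell_program")
}

#' Interpolate one expression program toward a reference program
#'
#' The fidelity dial: returns a program whose weights are
#' `(1 - delta) * base + delta * reference`, renormalized. `delta = 0`
#' leaves the base program unchanged; `delta = 1` reproduces the reference
#' exactly.
#'
#' @param base,reference [cell_program]s sharing the same gene axis.
#' @param delta Interpolation weight in [0, 1].
#' @return A [cell_program] named `<base>@delta=<delta>`.
#' @export
interpolate_program <- function(base, reference, delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (!identical(names(base$gene_weights), names(reference$gene_weights)))
    stop("programs must share the same gene axis")
  w <- (1 - delta) * base$gene_weights + delta * reference$gene_weights
  w <- w / sum(w)
  structure(list(name = sprintf("%s@delta=%g", base$name, delta),
                 gene_weights = w,
                 marker_genes = base$marker_genes),
            class = "cell_program")
}

#' Specify a synthetic single-cell dataset
#'
#' Describes a mixture of expression programs sampled at log-normal library
#' sizes, with dedicated mitochondrial (`mt-` prefixed) and ribosomal
#' (`Rps`/`Rpl` prefixed) gene blocks receiving fixed expected count
#' fractions, and an optional per-program fidelity value pulling each
#' program's weights toward a designated reference program.
#'
#' Defaults emulate the statistical structure of nanowell (Seq-Well-style)
#' UMI data from intestinal epithelium: library sizes centered near 2000
#' UMIs with log-normal spread keeping most cells in the 1000-8000 UMI
#' analysis window, 10.4% mitochondrial and 5.4% ribosomal count fractions.
#'
#' @param programs List of [cell_program]s sharing one gene axis.
#' @param proportions Mixture fractions, one per program, summing to 1.
#' @param n_cells Number of cells to draw.
#' @param library_size_log_mean,library_size_log_sd Parameters of the
#'   log-normal library-size law (natural-log scale).
#' @param mito_fraction,ribo_fraction Expected count fractions routed to the
#'   `mt-`/`Rps|Rpl` gene blocks.
#' @param fidelity Per-program delta in [0, 1]; `NULL` disables
#'   interpolation.
#' @param reference_program Index of the program the fidelity dial pulls
#'   toward; required when `fidelity` is set.
#' @param rng_seed Integer seed; the draw is bit-reproducible given the
#'   seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(programs, proportions, n_cells,
                           library_size_log_mean = log(2000),
                           library_size_log_sd = 0.4,
                           mito_fraction = 0.104,
                           ribo_fraction = 0.054,
                           fidelity = NULL,
                           reference_program = NULL,
                           rng_seed = 1L) {
  if (n_cells <= 0) stop("n_cells must be positive")
  if (length(proportions) != length(programs))
    stop("one mixture proportion per program required")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (!is.null(fidelity)) {
    if (is.null(reference_program))
      stop("fidelity requires a designated reference_program")
    if (length(fidelity) != length(programs))
      stop("one fidelity value per program required")
    if (any(fidelity < 0 | fidelity > 1)) stop("fidelity must lie in [0, 1]")
  }
  if (mito_fraction < 0 || ribo_fraction < 0 || mito_fraction + ribo_fraction >= 1)
    stop("mito_fraction + ribo_fraction must lie in [0, 1)")
  axes <- vapply(programs, function(p) paste(names(p$gene_weights), collapse = "\r"),
                 character(1))
  if (length(unique(axes)) != 1) stop("all programs must share one gene axis")
  structure(list(programs = programs, proportions = proportions,
                 n_cells = as.integer(n_cells),
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 mito_fraction = mito_fraction, ribo_fraction = ribo_fraction,
                 fidelity = fidelity, reference_program = reference_program,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Build the standard multi-program benchmark specification
#'
#' Convenience constructor for the simulator's reference scenario: uniform
#' background expression over `n_genes` biological genes plus `n_mito`
#' mitochondrial and `n_ribo` ribosomal genes, with `markers_per_program`
#' disjoint planted markers per program upweighted `marker_fold`-fold.
#' Program 1 plays the role of the in vivo reference population; rare
#' programs are supported through `proportions`.
#'
#' @param n_genes Number of biological (non-mito, non-ribo) genes, named
#'   `g0001`, `g0002`, ...
#' @param n_programs Number of expression programs.
#' @param markers_per_program Planted markers per program.
#' @param marker_fold Fold upweighting of planted markers.
#' @param proportions Mixture fractions; defaults to equal.
#' @param n_cells Total cells.
#' @param n_mito,n_ribo Sizes of the `mt-` and `Rps`/`Rpl` gene blocks.
#' @param fidelity,reference_program,rng_seed,... Passed to
#'   [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_benchmark_spec <- function(n_genes = 2000, n_programs = 3,
                                     markers_per_program = 20,
                                     marker_fold = 10,
                                     proportions = NULL,
                                     n_cells = 600,
                                     n_mito = 10, n_ribo = 20,
                                     fidelity = NULL,
                                     reference_program = NULL,
                                     rng_seed = 1L, ...) {
  if (is.null(proportions)) proportions <- rep(1 / n_programs, n_programs)
  bio <- sprintf("g%04d", seq_len(n_genes))
  mito <- sprintf("mt-%d", seq_len(n_mito))
  ribo <- c(sprintf("Rps%d", seq_len(ceiling(n_ribo / 2))),
            sprintf("Rpl%d", seq_len(floor(n_ribo / 2))))
  genes <- c(bio, mito, ribo)
  base_w <- stats::setNames(rep(1, length(genes)), genes)
  programs <- lapply(seq_len(n_programs), function(i) {
    lo <- (i - 1) * markers_per_program + 1
    hi <- i * markers_per_program
    if (hi > n_genes) stop("not enough genes for disjoint marker blocks")
    cell_program(sprintf("program%d", i), base_w,
                 marker_genes = bio[lo:hi], marker_fold = marker_fold)
  })
  synthetic_spec(programs, proportions, n_cells,
                 fidelity = fidelity, reference_program = reference_program,
                 rng_seed = rng_seed, ...)
}

#' Generate a synthetic UMI count matrix with ground truth
#'
#' For each cell: draw its program from the mixture proportions, draw a
#' library size from the log-normal law (rounded, clipped to >= 1), and
#' draw gene counts from a multinomial over the program's
#' (fidelity-interpolated, mito/ribo-rescaled) normalized weights.
#' Bit-reproducible given `spec$rng_seed`.
#'
#' @param spec A [synthetic_spec].
#' @return A list with elements `counts` (a [count_matrix]) and
#'   `ground_truth` (list with per-cell `labels`, per-program `markers`,
#'   and the `fidelity` used).
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  programs <- spec$programs
  if (!is.null(spec$fidelity)) {
    ref <- programs[[spec$reference_program]]
    programs <- lapply(seq_along(programs), function(i) {
      if (i == spec$reference_program) programs[[i]]
      else interpolate_program(programs[[i]], ref, spec$fidelity[i])
    })
  }
  genes <- names(programs[[1]]$gene_weights)
  is_mito <- startsWith(genes, "mt-")
  is_ribo <- startsWith(genes, "Rps") | startsWith(genes, "Rpl")
  weights <- lapply(programs, function(p) {
    w <- p$gene_weights
    # route fixed expected fractions to the mito/ribo blocks, rescale the rest
    if (any(is_mito) || any(is_ribo)) {
      bio_mass <- sum(w[!is_mito & !is_ribo])
      if (bio_mass <= 0) stop("program '", p$name, "' has zero biological weight")
      w[!is_mito & !is_ribo] <- w[!is_mito & !is_ribo] / bio_mass *
        (1 - spec$mito_fraction * any(is_mito) - spec$ribo_fraction * any(is_ribo))
      if (any(is_mito)) w[is_mito] <- spec$mito_fraction * w[is_mito] / sum(w[is_mito])
      if (any(is_ribo)) w[is_ribo] <- spec$ribo_fraction * w[is_ribo] / sum(w[is_ribo])
    }
    w / sum(w)
  })
  n <- spec$n_cells
  labels <- sample.int(length(programs), n, replace = TRUE,
                       prob = spec$proportions)
  lib <- pmax(1, round(stats::rlnorm(n, spec$library_size_log_mean,
                                     spec$library_size_log_sd)))
  counts <- matrix(0, nrow = n, ncol = length(genes),
                   dimnames = list(sprintf("cell%05d", seq_len(n)), genes))
  for (i in seq_len(n))
    counts[i, ] <- stats::rmultinom(1, lib[i], weights[[labels[i]]])
  gt <- list(labels = stats::setNames(labels, rownames(counts)),
             markers = lapply(spec$programs, function(p) p$marker_genes),
             fidelity = spec$fidelity)
  names(gt$markers) <- vapply(spec$programs, `[[`, character(1), "name")
  list(counts = count_matrix(counts, sample_label = "synthetic"),
       ground_truth = gt)
}
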