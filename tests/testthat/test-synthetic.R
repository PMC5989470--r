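test_that("multinomial totals equal the drawn library size exactly", {
  # degenerate log-normal (sd 0) pins every library at 2000 UMIs
  spec <- synthetic_benchmark_spec(n_genes = 200, n_programs = 1,
                                   proportions = 1, n_cells = 40,
                                   library_size_log_mean = log(2000),
                                   library_size_log_sd = 0, rng_seed = 3)
  sim <- generate_counts(spec)
  expect_true(all(rowSums(sim$counts) == 2000))
})

test_that("program mixing follows the stated proportions within binomial bounds", {
  spec <- synthetic_benchmark_spec(n_genes = 200, n_programs = 2,
                                   proportions = c(0.9, 0.1), n_cells = 1000,
                                   rng_seed = 11)
  sim <- generate_counts(spec)
  n1 <- sum(sim$ground_truth$labels == 1)
  bound <- 3 * sqrt(1000 * 0.9 * 0.1)
  expect_lt(abs(n1 - 900), bound)
  expect_lt(abs((1000 - n1) - 100), bound)
})

test_that("identical seed and spec reproduce bit-identical matrices", {
  spec <- synthetic_benchmark_spec(n_genes = 300, n_cells = 50, rng_seed = 5)
  a <- generate_counts(spec)
  b <- generate_counts(spec)
  expect_identical(unclass(a$counts)[, ], unclass(b$counts)[, ])
  expect_identical(a$ground_truth$labels, b$ground_truth$labels)
})

test_that("program interpolation is linear in the weights with identity endpoints", {
  w_base <- setNames(c(0.8, 0.2), c("gA", "gB"))
  w_ref <- setNames(c(0.2, 0.8), c("gA", "gB"))
  base <- cell_program("base", w_base)
  ref <- cell_program("ref", w_ref)
  expect_equal(interpolate_program(base, ref, 0)$gene_weights, base$gene_weights)
  expect_equal(interpolate_program(base, ref, 1)$gene_weights, ref$gene_weights)
  expect_equal(unname(interpolate_program(base, ref, 0.5)$gene_weights),
               c(0.5, 0.5))
  ref2 <- cell_program("ref2", setNames(c(0.5, 0.5), c("gA", "gC")))
  expect_error(interpolate_program(base, ref2, 0.5), "gene axis")
  expect_error(interpolate_program(base, ref, 1.5), "delta")
})

test_that("spec validation catches inconsistent mixtures and fidelity dials", {
  w <- setNames(rep(1, 4), c("a", "b", "c", "d"))
  p <- cell_program("p", w)
  expect_silent(synthetic_spec(list(p), 1, 10))
  expect_error(synthetic_spec(list(p, p), c(0.6, 0.6), 10), "sum to 1")
  expect_error(synthetic_spec(list(p), 1, 10, fidelity = 0.5),
               "reference_program")
  expect_error(cell_program("zero", setNames(c(0, 0), c("a", "b"))),
               "zero total weight")
})

test_that("empirical mitochondrial fraction converges to the spec value", {
  spec <- synthetic_benchmark_spec(n_genes = 500, n_programs = 1,
                                   proportions = 1, n_cells = 200,
                                   library_size_log_mean = log(10000),
                                   library_size_log_sd = 0,
                                   mito_fraction = 0.104,
                                   ribo_fraction = 0.054, rng_seed = 9)
  sim <- generate_counts(spec)
  qc <- compute_qc_metrics(sim$counts)
  # per-cell fraction is an average of 200 binomial(10000, 0.104) draws
  se <- sqrt(0.104 * (1 - 0.104) / 10000 / 200)
  expect_lt(abs(mean(qc$pct_mito) - 0.104), 3 * se)
  expect_lt(abs(mean(qc$pct_ribo) - 0.054), 3 * sqrt(0.054 * 0.946 / 10000 / 200))
})

test_that("planted markers separate their program at high AUC", {
  bench <- small_benchmark()
  truth <- toy_labels(bench$truth - 1L, names(bench$truth))
  for (prog in 1:3) {
    markers <- bench$sim$ground_truth$markers[[prog]]
    auc_tab <- roc_auc_marker(bench$nm, truth, prog - 1L)
    planted <- auc_tab$auc[match(markers, auc_tab$gene)]
    expect_true(all(planted > 0.9),
                info = sprintf("program %d min AUC %.3f", prog, min(planted)))
  }
})

test_that("marker-list scores rise strictly with the fidelity dial", {
  deltas <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(seq_along(deltas), function(i) {
    spec <- synthetic_benchmark_spec(n_genes = 800, n_programs = 2,
                                     proportions = c(0.5, 0.5), n_cells = 200,
                                     fidelity = c(0, deltas[i]),
                                     reference_program = 1L, rng_seed = 21)
    sim <- generate_counts(spec)
    nm <- normalize_log_scaled(sim$counts)
    sig <- gene_list(sim$ground_truth$markers[["program1"]], "planted")
    cells <- names(sim$ground_truth$labels)[sim$ground_truth$labels == 2]
    mean(score_cells(nm, sig)$scores[cells])
  }, numeric(1))
  expect_true(all(diff(means) > 0),
              info = paste(round(means, 5), collapse = " "))
})
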