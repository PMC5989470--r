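test_that("ROC AUC matches exhaustive pair counting on hand examples", {
  # in-group [3, 2], out-group [1, 0, 2]: 5 concordant + 1 tie -> 5.5/6
  v <- matrix(c(3, 2, 1, 0, 2), 5, 1,
              dimnames = list(sprintf("c%02d", 1:5), "gX"))
  lab <- toy_labels(c(1L, 1L, 0L, 0L, 0L))
  tab <- roc_auc_marker(toy_normalized(v), lab, 1L)
  expect_equal(tab$auc, 5.5 / 6)
  expect_equal(tab$mean_in, 2.5)
  expect_equal(tab$pct_out, 2 / 3)

  # constant gene: all pairs tied -> AUC exactly 0.5
  vc <- matrix(1, 5, 1, dimnames = list(sprintf("c%02d", 1:5), "gC"))
  expect_equal(roc_auc_marker(toy_normalized(vc), lab, 1L)$auc, 0.5)

  # gene detected in every in-cluster cell and nowhere else -> AUC 1
  vp <- matrix(c(2, 1, 0, 0, 0), 5, 1,
               dimnames = list(sprintf("c%02d", 1:5), "gP"))
  expect_equal(roc_auc_marker(toy_normalized(vp), lab, 1L)$auc, 1.0)

  expect_error(roc_auc_marker(toy_normalized(v), lab, 7L), "no cells")
  all_in <- toy_labels(rep(0L, 5))
  expect_error(roc_auc_marker(toy_normalized(v), all_in, 0L), "every cell")
})

test_that("ROC AUC equals the brute-force oracle and survives monotone transforms", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    n_in <- sample(2:(n - 2), 1)
    x <- rpois(n, 2)  # heavy ties
    v <- matrix(as.numeric(x), n, 1,
                dimnames = list(sprintf("c%03d", 1:n), "g"))
    lab <- toy_labels(c(rep(1L, n_in), rep(0L, n - n_in)),
                      sprintf("c%03d", 1:n))
    got <- roc_auc_marker(toy_normalized(v), lab, 1L)$auc
    expect_equal(got, auc_bruteforce(x[1:n_in], x[(n_in + 1):n]),
                 tolerance = 1e-12)
    # strictly monotone transform leaves ranks, hence the AUC, unchanged
    v2 <- matrix(sqrt(x) * 3 + x / 7, n, 1, dimnames = dimnames(v))
    expect_equal(roc_auc_marker(toy_normalized(v2), lab, 1L)$auc, got)
  }
})

test_that("bimodal LRT is null at identity and matches the longhand likelihood", {
  x <- c(0, 0, 1.5, 2.5, 3)
  r <- bimod_lrt(x, x)
  expect_equal(r$lrt_statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(18)
  x_in <- rep(0, 20)
  x_out <- abs(rnorm(20, 2))
  got <- bimod_lrt(x_in, x_out)
  oracle <- 2 * (zin_loglik_oracle(x_in) + zin_loglik_oracle(x_out) -
                   zin_loglik_oracle(c(x_in, x_out)))
  expect_equal(got$lrt_statistic, oracle, tolerance = 1e-10)
  expect_equal(got$p_value, pchisq(oracle, 3, lower.tail = FALSE),
               tolerance = 1e-10)

  # pooled fit ignores concatenation order
  set.seed(19)
  a <- ifelse(runif(30) < 0.4, 0, rnorm(30, 2))
  b <- ifelse(runif(25) < 0.6, 0, rnorm(25, 3))
  expect_equal(bimod_lrt(a, b)$lrt_statistic, bimod_lrt(b, a)$lrt_statistic,
               tolerance = 1e-12)
  expect_error(bimod_lrt(numeric(), a), "non-empty")
})

test_that("bimodal LRT handles degenerate groups through the sigma floor", {
  # single positive value and all-zero groups stay finite
  expect_true(is.finite(bimod_lrt(c(0, 0, 2), c(0, 0, 0))$lrt_statistic))
  expect_true(is.finite(bimod_lrt(c(1, 1, 1), c(2, 2, 2))$lrt_statistic))
  r <- bimod_lrt(rep(0, 10), rep(0, 10))
  expect_equal(r$lrt_statistic, 0)
})

test_that("Bonferroni adjustment caps, scales, and preserves order", {
  expect_equal(bonferroni_adjust(0.01, 100), 1.0)
  expect_equal(bonferroni_adjust(1e-6, 1000), 1e-3)
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  p <- sort(runif(50))
  adj <- bonferroni_adjust(p, 50)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_equal(adj, pmin(1, stats::p.adjust(p, "bonferroni", 50)))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})

test_that("derived signatures recover planted markers and respect the threshold", {
  bench <- small_benchmark()
  truth <- toy_labels(bench$truth - 1L, names(bench$truth))
  sig <- derive_signature(bench$nm, truth, 0L, auc_threshold = 0.65)
  planted <- bench$sim$ground_truth$markers[[1]]
  expect_true(all(planted %in% sig$genes))
  expect_true(all(diff(sig$auc) <= 0))  # sorted by decreasing AUC
  expect_equal(sig$threshold, 0.65)

  # impossible threshold yields an explicit empty signature with a warning
  expect_warning(empty <- derive_signature(bench$nm, truth, 0L,
                                           auc_threshold = 1.0),
                 "empty signature")
  expect_true(isTRUE(attr(empty, "empty_signature")))
  expect_length(empty$genes, 0)
})

test_that("pairwise bimodal DE ranks planted markers first", {
  bench <- small_benchmark()
  truth <- toy_labels(bench$truth - 1L, names(bench$truth))
  cells1 <- names(truth$labels)[truth$labels == 0]
  cells2 <- names(truth$labels)[truth$labels == 1]
  genes <- c(bench$sim$ground_truth$markers[[1]],
             bench$sim$ground_truth$markers[[2]], sprintf("g%04d", 101:150))
  de <- bimod_de(bench$nm, cells1, cells2, genes = genes)
  expect_true(all(de$p_adjusted >= de$p_value))
  planted <- c(bench$sim$ground_truth$markers[[1]],
               bench$sim$ground_truth$markers[[2]])
  expect_true(all(head(de$gene, 10) %in% planted))
  # markers of group 1 rise, markers of group 2 fall
  lfc1 <- de$log_fold_change[de$gene %in% bench$sim$ground_truth$markers[[1]]]
  lfc2 <- de$log_fold_change[de$gene %in% bench$sim$ground_truth$markers[[2]]]
  expect_true(all(lfc1 > 0) && all(lfc2 < 0))
})
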