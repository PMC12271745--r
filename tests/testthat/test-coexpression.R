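test_that("count preprocessing filters low expression and scales by median ratios", {
  set.seed(24)
  n_s <- 20
  counts <- matrix(rnbinom(50 * n_s, mu = 200, size = 10), 50, n_s,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:n_s)))
  # a gene at <= 10 reads in 85% of samples is dropped at the (10, 0.8) rule
  low <- c(rep(2, 17), rep(50, 3))
  counts[1, ] <- low
  pe <- preprocess_counts(counts, rep(c("a", "b"), each = 10))
  expect_false("g1" %in% rownames(pe$norm))
  expect_equal(pe$ledger$n_filtered, 1L)

  # sample that is an exact x2 multiple gets a x2 size factor
  c2 <- cbind(counts[-1, 1:5], counts[-1, 1] * 2)
  colnames(c2) <- paste0("s", 1:6)
  pe2 <- preprocess_counts(c2, rep("a", 6))
  expect_equal(pe2$size_factors[[6]] / pe2$size_factors[[1]], 2,
               tolerance = 1e-12)

  # min_reads 0 keeps everything expressed
  pe0 <- preprocess_counts(counts, rep(c("a", "b"), each = 10), min_reads = 0)
  expect_equal(nrow(pe0$norm), 50)

  expect_error(preprocess_counts(matrix(c(0, 3, 3, 0), 2, 2,
                                        dimnames = list(c("a", "b"), NULL)),
                                 rep("x", 2), min_reads = -1),
               class = "chromanet_degenerate_error")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(25)
  counts <- matrix(rnbinom(200 * 12, mu = 300, size = 5), 200, 12,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  pe <- preprocess_counts(counts, rep("a", 12), min_reads = 0)
  ref <- DESeq2::estimateSizeFactorsForMatrix(pe$counts)
  expect_equal(unname(pe$size_factors), unname(ref), tolerance = 1e-8)
})

test_that("MI estimator is symmetric, rank-invariant and matches oracles", {
  set.seed(26)
  x <- rnorm(1000); y <- 0.5 * x + rnorm(1000)
  expect_identical(estimate_mi(x, y), estimate_mi(y, x))
  # strictly monotone transforms leave the estimate unchanged
  expect_equal(estimate_mi(exp(2 * x), y), estimate_mi(x, y))
  expect_equal(estimate_mi(x, y^3 + 5 * y), estimate_mi(x, y))

  # bivariate Gaussian oracle: MI = -log(1 - rho^2) / 2
  set.seed(27)
  n <- 5000; rho <- 0.9
  xg <- rnorm(n); yg <- rho * xg + sqrt(1 - rho^2) * rnorm(n)
  truth <- -0.5 * log(1 - rho^2)
  expect_lt(abs(estimate_mi(xg, yg) - truth) / truth, 0.15)

  # independent Gaussians stay near zero after bias correction
  mis <- vapply(1:10, function(s) {
    set.seed(100 + s); estimate_mi(rnorm(1000), rnorm(1000))
  }, numeric(1))
  expect_lt(mean(mis), 0.02)

  # perfect dependence saturates near log(grid size)
  expect_gt(estimate_mi(1:1000, (1:1000)^2) / log(14), 0.95)

  expect_true(attr(estimate_mi(rep(1, 50), rnorm(50)), "degenerate"))
  expect_error(estimate_mi(1:5, 1:5))
})

test_that("batch MI matrix equals the scalar estimator pair by pair", {
  set.seed(28)
  mat <- matrix(rnorm(8 * 60), 8, 60, dimnames = list(paste0("g", 1:8), NULL))
  mm <- chromanet:::mi_matrix(mat)
  for (a in 1:7) for (b in (a + 1):8) {
    expect_equal(mm[a, b], as.numeric(estimate_mi(mat[a, ], mat[b, ])),
                 tolerance = 1e-12)
  }
})

test_that("MI threshold estimation is seeded and consistent with its null", {
  set.seed(29)
  mat <- matrix(rnorm(40 * 80), 40, 80, dimnames = list(paste0("g", 1:40),
                                                        NULL))
  thr05 <- estimate_mi_threshold(mat, pvalue = 0.05, n_null = 4000, seed = 1)
  q95 <- attr(thr05, "null_quantile95")
  expect_lt(abs(as.numeric(thr05) - q95) / q95, 0.10)

  thr8 <- estimate_mi_threshold(mat, pvalue = 1e-8, n_null = 4000, seed = 1)
  expect_gt(as.numeric(thr8), as.numeric(thr05))
  # extrapolated threshold exceeds anything the null sample produced
  set.seed(1)
  null_max <- max(vapply(1:2000, function(k) {
    estimate_mi(mat[sample.int(40, 1), ], mat[sample.int(40, 1), sample(80)])
  }, numeric(1)))
  expect_gt(as.numeric(thr8), null_max)

  expect_identical(as.numeric(estimate_mi_threshold(mat, 1e-8, 4000, seed = 7)),
                   as.numeric(estimate_mi_threshold(mat, 1e-8, 4000, seed = 7)))
})

test_that("bootstrap consensus keeps supported pairs under the Poisson test", {
  # Poisson tail arithmetic: support 100 of 100 against lambda 0.5
  expect_lt(ppois(99, 0.5, lower.tail = FALSE), 1e-10)

  set.seed(30)
  ex <- simulate_expression_pair(
    expr_sim_params(n_genes = 30, n_samples_normal = 80, n_samples_tumor = 10,
                    n_modules = 2, module_size = 6,
                    within_module_correlation = 0.85,
                    module_rewire_fraction = 0, seed = 31))
  pe <- preprocess_counts(ex$normal, rep("n", 80), min_reads = 0)
  thr <- estimate_mi_threshold(pe$norm, pvalue = 1e-6, n_null = 3000, seed = 2)
  net <- bootstrap_consensus_network(pe$norm, B = 40, mi_threshold = thr,
                                     seed = 3)
  expect_s3_class(net, "MINetwork")
  expect_true(all(net$support > 0))
  expect_true(all(net$pvalue < 0.05 / attr(net, "n_candidates")))
  mod <- ex$truth$module_normal
  same <- mod[net$gene_a] == mod[net$gene_b] &
    !is.na(mod[net$gene_a]) & !is.na(mod[net$gene_b])
  expect_gt(mean(same), 0.8)

  # same seed, same network; lowering alpha never adds edges
  net2 <- bootstrap_consensus_network(pe$norm, B = 40, mi_threshold = thr,
                                      seed = 3)
  expect_identical(as.data.frame(net), as.data.frame(net2))
  net_strict <- bootstrap_consensus_network(pe$norm, B = 40,
                                            mi_threshold = thr,
                                            alpha = 0.001, seed = 3)
  expect_true(all(paste(net_strict$gene_a, net_strict$gene_b) %in%
                    paste(net$gene_a, net$gene_b)))

  # a single gene cannot form pairs
  expect_warning(empty <- bootstrap_consensus_network(
    pe$norm[1, , drop = FALSE], B = 10, mi_threshold = 0.5))
  expect_equal(nrow(empty), 0)
})
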