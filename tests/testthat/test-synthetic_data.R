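test_that("simulated maps conserve mass and honour the tumor loss fraction", {
  p <- hic_sim_params(n_bins = 120, total_contacts = 1e5,
                      tumor_loss_fraction = 0.3, seed = 2)
  sim <- simulate_hic_pair(p)
  expect_equal(sim$normal$total, 1e5)
  expect_equal(sim$tumor$total, 7e4)  # exact: multinomial conserves mass
  expect_true(all(sim$normal$entries$count == round(sim$normal$entries$count)))
  # bit-reproducible given the seed
  sim2 <- simulate_hic_pair(p)
  expect_identical(sim$normal$entries, sim2$normal$entries)
  expect_identical(sim$truth$peaks_tumor, sim2$truth$peaks_tumor)
})

test_that("pure-decay maps decay monotonically across metabins", {
  p <- hic_sim_params(n_bins = 150, total_contacts = 3e5, peak_count = 0,
                      bias_sd = 0, seed = 5)
  sim <- simulate_hic_pair(p)
  m <- chromanet:::contact_map_dense(sim$normal)
  nb <- sim$normal$n_bins
  counts <- unlist(lapply(1:(nb - 1), function(d) {
    idx <- seq_len(nb - d); m[cbind(idx, idx + d)]
  }))
  dists <- rep(1:(nb - 1), times = (nb - 1):1)
  grp <- (seq_along(dists) - 1) %/% 200
  mb <- tapply(counts[order(dists)], grp, mean)
  # non-increasing up to multinomial noise; assert on strict violations
  expect_true(all(diff(mb) <= 1e-9 + 0.2 * head(mb, -1)))
  expect_lt(mb[length(mb)], mb[1] / 10)
  # realized decay tracks the analytic p(d) ~ d^-alpha within 10% (mid range)
  md <- tapply(sort(dists), grp, mean)
  z <- sum((150 - 1:149) / (1:149))
  expected <- 3e5 * (1 / md) / z
  mid <- md > quantile(md, 0.1) & md < quantile(md, 0.9)
  expect_lt(max(abs(mb[mid] / expected[mid] - 1)), 0.10)
})

test_that("tumor rewiring and truncation behave as planted", {
  p <- hic_sim_params(n_bins = 100, total_contacts = 1e5, peak_count = 30,
                      rewire_fraction = 1, truncation_distance = 1e6,
                      seed = 3)
  sim <- simulate_hic_pair(p)
  kn <- paste(sim$truth$peaks_normal$bin_i, sim$truth$peaks_normal$bin_j)
  kt <- paste(sim$truth$peaks_tumor$bin_i, sim$truth$peaks_tumor$bin_j)
  expect_length(intersect(kn, kt), 0)  # full rewire: disjoint peak sets
  # beyond truncation the tumor mean count drops below the normal mean
  mn <- chromanet:::contact_map_dense(sim$normal)
  mt <- chromanet:::contact_map_dense(sim$tumor)
  far <- which(abs(row(mn) - col(mn)) * 40000 > 1e6 & row(mn) < col(mn))
  expect_lt(mean(mt[far]), mean(mn[far]))
})

test_that("forced peak pairs are planted alongside random peaks", {
  forced <- data.frame(bin_i = c(2L, 10L), bin_j = c(5L, 11L))
  p <- hic_sim_params(n_bins = 60, total_contacts = 5e4, peak_count = 5,
                      peak_pairs = forced, seed = 4)
  sim <- simulate_hic_pair(p)
  kn <- paste(sim$truth$peaks_normal$bin_i, sim$truth$peaks_normal$bin_j)
  expect_true(all(paste(forced$bin_i, forced$bin_j) %in% kn))
  expect_equal(length(kn), 7)
})

test_that("expression generator hits its correlation targets", {
  # two genes sharing one module at rho = 0.9, many samples
  p <- expr_sim_params(n_genes = 2, n_samples_normal = 500,
                       n_samples_tumor = 10, n_modules = 1, module_size = 2,
                       within_module_correlation = 0.9,
                       module_rewire_fraction = 0, seed = 6)
  sim <- simulate_expression_pair(p)
  r <- cor(log1p(sim$normal[1, ]), log1p(sim$normal[2, ]))
  expect_lt(abs(r - 0.9), 0.1)

  # rho = 0: mean absolute inter-gene correlation near zero
  p0 <- expr_sim_params(n_genes = 30, n_samples_normal = 150,
                        n_samples_tumor = 10, n_modules = 3, module_size = 5,
                        within_module_correlation = 0,
                        module_rewire_fraction = 0, seed = 7)
  s0 <- simulate_expression_pair(p0)
  cm <- cor(t(log1p(s0$normal)))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)

  expect_error(expr_sim_params(within_module_correlation = 1),
               class = "chromanet_parameter_error")
})

test_that("module rewiring is recorded in the truth and off by default 0", {
  p <- expr_sim_params(module_rewire_fraction = 0, seed = 8)
  sim <- simulate_expression_pair(p)
  expect_identical(sim$truth$module_normal, sim$truth$module_tumor)
  expect_length(sim$truth$changed_genes, 0)

  p2 <- expr_sim_params(module_rewire_fraction = 0.4, seed = 8)
  sim2 <- simulate_expression_pair(p2)
  ch <- sim2$truth$changed_genes
  expect_equal(length(ch), round(0.4 * 80))
  expect_true(all(sim2$truth$module_normal[ch] != sim2$truth$module_tumor[ch]))
})

test_that("synthetic annotation partitions bins into C, R and N", {
  g <- simulate_genome_annotation(n_bins = 100, gene_density = 0.5,
                                  ncrna_fraction = 0.2, seed = 9)
  expect_equal(nrow(g$genes), 50)
  expect_equal(length(unique(g$truth$placement)), 50)  # one TSS per bin
  cls <- chromanet:::classify_bins(100, 40000, g$genes, "chrS")
  expect_equal(sum(cls$types == "C") + sum(cls$types == "R") +
                 sum(cls$types == "N"), 100)

  g0 <- simulate_genome_annotation(n_bins = 100, ncrna_fraction = 0, seed = 9)
  expect_false(any(g0$genes$biotype == "ncRNA"))

  gb <- simulate_genome_annotation(n_bins = 200, blacklist_fraction = 0.1,
                                   seed = 10)
  expect_equal(nrow(gb$blacklist), 20)
  expect_equal(sum(gb$blacklist$end - gb$blacklist$start), 20 * 40000)

  expect_error(simulate_genome_annotation(gene_density = 1.4),
               class = "chromanet_parameter_error")
})
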