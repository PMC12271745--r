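test_that("Jaccard similarity over nodes, edges and edge types", {
  a <- make_net(rbind(c(0, 1), c(1, 2)))
  b <- make_net(rbind(c(1, 2), c(2, 3)))
  expect_equal(jaccard_similarity(a, a, "nodes"), 1)
  expect_equal(jaccard_similarity(a, a, "edges"), 1)
  expect_equal(jaccard_similarity(a, b, "edges"), 1 / 3)
  expect_equal(jaccard_similarity(a, b, "nodes"), 1 / 2)  # {0,1,2} vs {1,2,3}
  d <- make_net(rbind(c(5, 6), c(7, 8)))
  expect_equal(jaccard_similarity(a, d, "edges"), 0)
  expect_equal(jaccard_similarity(a, b, "edges"),
               jaccard_similarity(b, a, "edges"))  # symmetry
  st <- jaccard_similarity(a, b, "edge_type")
  expect_named(st, "N-N")
  expect_equal(unname(st), 1 / 3)
  # different grids rejected
  other <- local({
    bins <- bin_table(c(chr2 = 12 * 40000), 40000)
    e <- data.frame(chrom = "chr2", bin_i = 0L, bin_j = 1L, count = 10,
                    distance_bp = 40000, omega = 2, pvalue = 1e-6,
                    qvalue = 1e-4, zscore = 1, edge_type = NA_character_)
    build_chromosome_network(e, bins)
  })
  expect_error(jaccard_similarity(a, other, "edges"))
})

test_that("edge-count log fold change and logFC matrices", {
  a <- make_net(t(combn(0:4, 2)))       # 10 edges
  b <- make_net(t(combn(0:4, 2))[1:5, ])  # 5 edges
  expect_equal(interaction_count_logfc(a, b), -1)
  expect_error(interaction_count_logfc(make_net(matrix(numeric(0), 0, 2)), a),
               class = "chromanet_degenerate_error")

  m <- contact_map("chrS", data.frame(bin_i = c(0L, 1L), bin_j = c(1L, 2L),
                                      count = c(4, 6)), 4)
  expect_equal(logfc_matrix(m, m)$log2fc, c(0, 0))
  m2 <- contact_map("chrS", data.frame(bin_i = 0L, bin_j = 1L, count = 9), 4)
  fc <- logfc_matrix(m, m2, pseudocount = 1)
  expect_equal(fc$log2fc[fc$bin_i == 0 & fc$bin_j == 1], 1)  # (9+1)/(4+1)
  expect_error(logfc_matrix(m, m2, pseudocount = 0))
})

test_that("tumor decay curve falls below normal beyond the truncation", {
  sim <- simulate_hic_pair(hic_sim_params(n_bins = 150, total_contacts = 4e5,
                                          peak_count = 0, bias_sd = 0,
                                          tumor_loss_fraction = 0.3,
                                          truncation_distance = 2e6,
                                          seed = 20))
  dn <- decay_curve(ice_balance(sim$normal)$map)
  dt <- decay_curve(ice_balance(sim$tumor)$map)
  far <- dn$distance_bp > 2e6
  expect_true(all(dt$mean_count[far] < dn$mean_count[far]))
})

test_that("node metrics: degree and absolute-Z-weighted degree", {
  net <- make_net(rbind(c(0, 1), c(0, 2)), zscore = c(1.5, -0.5))
  nm <- node_metrics(net)
  expect_equal(nm$degree[nm$node == "0"], 2L)
  expect_equal(nm$z_weighted_degree[nm$node == "0"], 2.0)
  expect_equal(nm$z_weighted_degree[nm$node == "2"], 0.5)
  set.seed(21)
  for (r in 1:5) {
    ij <- t(combn(sample(0:11, 5), 2))
    nr <- node_metrics(make_net(ij, zscore = rnorm(nrow(ij))))
    expect_equal(sum(nr$degree), 2 * nrow(ij))
  }
})

test_that("node dissimilarity is one minus the neighbour-set Jaccard", {
  a <- make_net(rbind(c(0, 1), c(0, 2), c(3, 4)))
  b <- make_net(rbind(c(0, 1), c(0, 5), c(3, 4)))
  di <- node_dissimilarity_profile(a, b)
  rec <- setNames(di$DI, di$node)
  expect_equal(unname(rec["3"]), 0)          # identical neighbours
  expect_equal(unname(rec["0"]), 1 - 1 / 3)  # {1,2} vs {1,5}
  expect_equal(unname(rec["1"]), 0)
  expect_true(!is.unsorted(di$DI))
  # disjoint neighbourhoods score 1
  c1 <- make_net(rbind(c(0, 1), c(2, 3)))
  c2 <- make_net(rbind(c(0, 4), c(2, 3)))
  dic <- node_dissimilarity_profile(c1, c2)
  expect_equal(setNames(dic$DI, dic$node)[["0"]], 1)
  expect_error(node_dissimilarity_profile(a, make_net(rbind(c(6, 7)))),
               class = "chromanet_degenerate_error")
})

test_that("kneedle finds the analytic elbow of a piecewise-linear ramp", {
  vals <- c(rep(0.1, 80), 0.1 + (1:20) * 0.045)  # flat then linear to 1.0
  kn <- kneedle_threshold(vals)
  expect_equal(kn$index, 80L)
  expect_equal(kn$threshold, 0.1)

  expect_error(kneedle_threshold(seq(0, 1, length.out = 50)),
               class = "chromanet_degenerate_error")  # pure ramp: no knee
  expect_error(kneedle_threshold(rep(0.3, 10)),
               class = "chromanet_degenerate_error")
  expect_error(kneedle_threshold(c(1, 2)),
               class = "chromanet_degenerate_error")

  step <- c(rep(0.05, 40), rep(0.9, 10))
  ks <- kneedle_threshold(step)
  expect_equal(ks$index, 40L)
})

test_that("kneedle separates preserved from rewired cohorts", {
  set.seed(22)
  di <- sort(c(runif(80, 0, 0.06), runif(20, 0.74, 0.86)))
  truth <- di > 0.5
  kn <- kneedle_threshold(di)
  called_rewired <- di > kn$threshold
  expect_gte(mean(called_rewired == truth), 0.95)
})

test_that("hypergeometric enrichment matches closed forms and brute force", {
  universe <- paste0("g", 1:100)
  sets <- list(hit = universe[1:10], other = universe[11:40])
  res <- hypergeometric_enrichment(universe[1:10], universe, sets)
  # query == set: single support point, p = 1 / C(100, 10)
  expect_equal(res$pvalue[res$set == "hit"], 1 / choose(100, 10))
  expect_equal(res$pvalue[res$set == "other"], 1)  # empty overlap
  expect_true(res$significant[res$set == "hit"])

  # overlap at its independence expectation is unremarkable
  set.seed(23)
  q <- universe[1:50]
  s <- list(s = universe[seq(1, 100, by = 2)])  # overlap 25 = 50*50/100
  r2 <- hypergeometric_enrichment(q, universe, s)
  expect_gt(r2$pvalue[1], 0.3)

  # brute-force enumeration of the tail on a small universe
  uni <- paste0("u", 1:20)
  query <- uni[1:8]
  set <- uni[c(1:5, 15:18)]
  k <- length(intersect(query, set))
  brute <- 0
  for (x in k:min(length(set), length(query))) {
    brute <- brute + choose(length(set), x) *
      choose(20 - length(set), 8 - x) / choose(20, 8)
  }
  r3 <- hypergeometric_enrichment(query, uni, list(s = set))
  expect_equal(r3$pvalue, brute, tolerance = 1e-12)

  expect_error(hypergeometric_enrichment(q, character(), sets))
})

test_that("GMT reader parses sets and rejects short lines", {
  p <- withr::local_tempfile()
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2"), p)
  g <- read_gmt(p)
  expect_equal(g$setA, c("g1", "g2", "g3"))
  expect_equal(g$setB, "g2")
  writeLines("bad\tonly-two-fields", p)
  expect_error(read_gmt(p), class = "chromanet_format_error")
})
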