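test_that("genes map to TSS-containing bins with the half-open convention", {
  bins <- bin_table(c(chrS = 10 * 40000), 40000)
  genes <- data.frame(gene_id = c("a", "b", "c"), symbol = c("A", "B", "C"),
                      chrom = "chrS", strand = "+",
                      tss = c(40000, 39999, 200000),
                      biotype = "coding", stringsAsFactors = FALSE)
  gm <- map_genes_to_bins(genes, bins)
  expect_equal(gm$bin_id, c(1L, 0L, 5L))
  # blacklisted bin leaves its gene unmapped and counted
  excl <- rep(FALSE, 10); excl[6] <- TRUE  # bin 5
  gm2 <- map_genes_to_bins(genes, bins, excluded_bins = excl)
  expect_equal(nrow(gm2), 2)
  expect_equal(attr(gm2, "n_unmapped"), 1L)
  genes$tss[1] <- 4e6
  expect_error(map_genes_to_bins(genes, bins))
})

test_that("multilayer assembly namespaces layers and weights interlayer edges", {
  hic <- make_net(rbind(c(0, 1)), zscore = 2)
  mi <- structure(data.frame(gene_a = "ga", gene_b = "gb", mi = 0.6,
                             support = 50L, pvalue = 1e-12,
                             stringsAsFactors = FALSE),
                  class = c("MINetwork", "data.frame"))
  gm <- data.frame(gene_id = c("ga", "gb"), bin_id = c(0L, 1L))
  ml <- assemble_multilayer(hic, mi, gm)
  expect_equal(igraph::vcount(ml), 4)
  expect_equal(igraph::ecount(ml), 4)  # 1 hic + 1 mi + 2 interlayer
  lay <- igraph::E(ml)$layer
  w <- igraph::E(ml)$weight
  expect_equal(sort(lay), c("hic", "interlayer", "interlayer", "mi"))
  expect_true(all(w[lay == "interlayer"] == 1))
  expect_equal(w[lay == "hic"], 2)   # |zscore| scheme
  expect_equal(w[lay == "mi"], 0.6)

  # layer predicates hold for every edge
  vl <- setNames(igraph::V(ml)$layer, igraph::V(ml)$name)
  el <- igraph::as_edgelist(ml)
  for (k in seq_len(nrow(el))) {
    ends <- sort(unname(vl[el[k, ]]))
    expect_equal(ends, switch(lay[k],
                              hic = c("HIC", "HIC"),
                              mi = c("MI", "MI"),
                              interlayer = c("HIC", "MI")))
  }

  # empty MI layer leaves the chromatin layer intact
  ml0 <- assemble_multilayer(hic, chromanet:::empty_mi_network(),
                             gm[0, , drop = FALSE])
  expect_equal(igraph::vcount(ml0), 2)
  expect_equal(igraph::ecount(ml0), 1)

  # a gene whose bin is not a chromatin node stays unlinked
  gm2 <- data.frame(gene_id = c("ga", "gb"), bin_id = c(0L, 7L))
  ml2 <- assemble_multilayer(hic, mi, gm2)
  expect_equal(igraph::graph_attr(ml2, "n_unlinked"), 1)
})

test_that("community detection is seeded and splits weakly joined cliques", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::E(g)$weight <- c(rep(1, 20), 0.1)
  igraph::V(g)$name <- paste0("n", 1:10)
  cl <- detect_communities(g, seed = 1)
  expect_equal(length(unique(cl$membership)), 2)
  expect_equal(length(unique(cl$membership[1:5])), 1)
  expect_equal(length(unique(cl$membership[6:10])), 1)
  expect_identical(detect_communities(g, seed = 1)$membership, cl$membership)

  single <- igraph::make_graph(c("a", "b"), directed = FALSE)
  igraph::E(single)$weight <- 1
  expect_equal(length(unique(detect_communities(single, 1)$membership)), 1)

  expect_error(detect_communities(igraph::make_empty_graph(0)),
               class = "chromanet_degenerate_error")
})

test_that("label alignment makes membership change permutation-invariant", {
  a <- setNames(c(1, 1, 1, 2, 2, 3, 3), paste0("n", 1:7))
  b_perm <- setNames(c(9, 9, 9, 4, 4, 7, 7), paste0("n", 1:7))
  st <- membership_change_stats(a, b_perm)
  expect_equal(st$overall_pct, 0)
  mapping <- align_communities(a, b_perm)
  expect_equal(unname(mapping[c("9", "4", "7")]), c("1", "2", "3"))

  # one community split in half: the larger-overlap half keeps the label
  a2 <- setNames(rep(1, 6), paste0("m", 1:6))
  b2 <- setNames(c(1, 1, 1, 1, 2, 2), paste0("m", 1:6))
  map2 <- align_communities(a2, b2)
  expect_equal(unname(map2["1"]), "1")
  expect_match(unname(map2["2"]), "^unmatched_")

  # all moved
  st_all <- membership_change_stats(
    setNames(c(1, 1, 2, 2), paste0("x", 1:4)),
    setNames(c(2, 2, 1, 1), paste0("x", c(3, 4, 1, 2))))
  expect_equal(st_all$n_shared, 4)

  expect_error(membership_change_stats(a, setNames(1, "zz")),
               class = "chromanet_degenerate_error")
})

test_that("planted community reassignment is recovered within tolerance", {
  cp <- simulate_community_pair(n_nodes = 60, n_modules = 4,
                                move_fraction = 0.3, seed = 32)
  ca <- detect_communities(cp$netA, seed = 42)
  cb <- detect_communities(cp$netB, seed = 42)
  st <- membership_change_stats(ca, cb, layers = cp$truth$layers)
  expect_lt(abs(st$overall_pct - 30), 5)

  # chromatin-only rewiring shows up as layer asymmetry
  cph <- simulate_community_pair(n_nodes = 60, n_modules = 4,
                                 move_fraction = 0.3, move_layers = "HIC",
                                 seed = 33)
  sth <- membership_change_stats(detect_communities(cph$netA, 42),
                                 detect_communities(cph$netB, 42),
                                 layers = cph$truth$layers)
  expect_gt(sth$per_layer_pct[["HIC"]], sth$per_layer_pct[["MI"]])
})

test_that("structure-expression analysis classifies planted change quadrants", {
  sc <- simulate_coupled_pair(n_pairs = 150, seed = 34)
  se <- structure_expression_analysis(sc$hicA, sc$hicB, sc$miA, sc$miB,
                                      sc$gene_bin_map)
  truth <- sc$truth$quadrant[paste(se$gene_a, se$gene_b)]
  sig <- se$quadrant != "ns"
  expect_gte(mean(se$quadrant[sig] == truth[sig]), 0.9)
  # quadrants partition the pairs
  expect_true(all(se$quadrant %in% c("both-up", "both-down", "hic-up-mi-down",
                                     "hic-down-mi-up", "ns")))

  # copy-constructed changes (delta_hic == delta_mi per pair) correlate at 1
  n <- 10
  f <- seq(0.2, 2, length.out = n)
  gm <- data.frame(gene_id = c(paste0("x", 1:n), paste0("y", 1:n)),
                   bin_id = c(2L * (1:n) - 2L, 2L * (1:n) - 1L))
  mk_h <- function(counts) data.frame(
    chrom = "chrS", bin_i = 2L * (1:n) - 2L, bin_j = 2L * (1:n) - 1L,
    count = counts, distance_bp = 40000, omega = NA_real_, pvalue = NA_real_,
    qvalue = 1e-6, zscore = NA_real_, edge_type = NA_character_,
    stringsAsFactors = FALSE)
  mk_m <- function(mi) structure(
    data.frame(gene_a = paste0("x", 1:n), gene_b = paste0("y", 1:n), mi = mi,
               support = 100L, pvalue = 0, stringsAsFactors = FALSE),
    class = c("MINetwork", "data.frame"))
  se_copy <- structure_expression_analysis(
    mk_h(rep(20, n)), mk_h(21 * 2^f - 1),
    mk_m(rep(0.5, n)), mk_m(0.51 * 2^f - 0.01), gm)
  expect_equal(attr(se_copy, "r_delta"), 1, tolerance = 1e-9)

  # decoupled simulation: no correlation between the layers' changes
  scd <- simulate_coupled_pair(n_pairs = 600, coupled = FALSE,
                               ns_fraction = 0, seed = 35)
  sed <- structure_expression_analysis(scd$hicA, scd$hicB, scd$miA, scd$miB,
                                       scd$gene_bin_map)
  expect_lt(abs(attr(sed, "r_delta")), 0.1)

  expect_error(structure_expression_analysis(
    sc$hicA[1, ], sc$hicB[1, ], sc$miA[0, ], sc$miB[0, ], sc$gene_bin_map),
    class = "chromanet_degenerate_error")
})
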