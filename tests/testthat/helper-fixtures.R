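# Shared fixtures and independent oracles, built in code at test time.

# tiny HiC-Pro dialect files: 3 bins of chr1 (+1 of chr2), triplets as given
write_tiny_hicpro <- function(triplets = data.frame(i = c(1, 2),
                                                    j = c(2, 3),
                                                    count = c(5, 7))) {
  dir <- tempfile("hicpro")
  dir.create(dir)
  bed <- file.path(dir, "bins.bed")
  mat <- file.path(dir, "mat.matrix")
  writeLines(c("chr1\t0\t40000\t1", "chr1\t40000\t80000\t2",
               "chr1\t80000\t120000\t3", "chr2\t0\t40000\t4"), bed)
  utils::write.table(triplets, mat, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(bed = bed, mat = mat)
}

# brute-force NCHG pmf: direct weights in ordinary double arithmetic
# (exact to ~1e-14 for n <= 200); independent of the package's log-space path
oracle_nchg_pmf <- function(k, n, ni, nj, omega) {
  kmin <- max(0, nj - (2 * n - ni))
  kmax <- min(ni, nj)
  ks <- kmin:kmax
  # rescale each factor to <= 1 so the direct product cannot overflow;
  # normalization cancels the scale factors
  t1 <- choose(ni, ks); t1 <- t1 / max(t1)
  t2 <- choose(2 * n - ni, nj - ks); t2 <- t2 / max(t2)
  lw <- ks * log(omega)
  t3 <- exp(lw - max(lw))
  w <- t1 * t2 * t3
  out <- numeric(length(k))
  inside <- k >= kmin & k <= kmax
  out[inside] <- w[k[inside] - kmin + 1] / sum(w)
  out
}

oracle_nchg_tail <- function(k, n, ni, nj, omega) {
  kmax <- min(ni, nj)
  if (k > kmax) return(0)
  sum(oracle_nchg_pmf(max(k, 0):kmax, n, ni, nj, omega))
}

# brute-force BH step-up definition: q_i = min_{j : p_(j) >= p_(i)} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# reference Sinkhorn-Knopp balancing run to tight convergence on a dense matrix
oracle_sinkhorn_bias <- function(m, iters = 10000) {
  b <- rep(1, nrow(m))
  for (it in seq_len(iters)) {
    s <- rowSums(m / outer(b, b))
    b <- b * s / mean(s)
  }
  b / mean(b)
}

# tiny chromatin network from an explicit edge list (bin ids on one chromosome)
make_net <- function(edges_ij, n_bins = 12, zscore = NULL, counts = NULL,
                     genes = NULL, q = 1e-4) {
  bins <- bin_table(c(chrS = n_bins * 40000), 40000)
  if (nrow(edges_ij) == 0) {
    edges <- chromanet:::empty_edge_table()
  } else {
    edges <- data.frame(
      chrom = "chrS", bin_i = edges_ij[, 1], bin_j = edges_ij[, 2],
      count = if (is.null(counts)) rep(10, nrow(edges_ij)) else counts,
      distance_bp = (edges_ij[, 2] - edges_ij[, 1]) * 40000,
      omega = 2, pvalue = q / 10, qvalue = q,
      zscore = if (is.null(zscore)) rep(1, nrow(edges_ij)) else zscore,
      edge_type = NA_character_, stringsAsFactors = FALSE)
  }
  build_chromosome_network(edges, bins, genes = genes, q_threshold = 1e-3)
}
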