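#' Filter and normalize a raw count matrix
#'
#' Drops low-expression genes (count `<= min_reads` in more than
#' `max_low_fraction` of samples, both conditions pooled) and computes
#' median-of-ratios size factors: the reference is the per-gene geometric mean
#' over genes with all-positive counts, and each sample's factor is the median
#' ratio of its counts to the reference. Normalized values are
#' `count / size_factor`.
#'
#' @param counts non-negative integer matrix, genes x samples (rownames =
#'   gene ids).
#' @param condition per-sample condition labels.
#' @param gene_chrom optional named chromosome assignment per gene.
#' @param min_reads,max_low_fraction low-expression filter (defaults: <= 10
#'   reads in > 80% of samples).
#' @return an `ExpressionMatrix`: list with `counts` (filtered raw), `norm`
#'   (normalized), `size_factors`, `condition`, `gene_chrom`, `ledger`.
#' @export
preprocess_counts <- function(counts, condition, gene_chrom = NULL,
                              min_reads = 10, max_low_fraction = 0.8) {
  cn_assert(all(counts >= 0) && all(counts == round(counts)),
            "raw counts must be non-negative integers")
  cn_assert(length(condition) == ncol(counts), "condition length mismatch")
  low <- rowMeans(counts <= min_reads) > max_low_fraction
  kept <- counts[!low, , drop = FALSE]
  cn_assert(nrow(kept) > 0, "no genes pass the expression filter",
            "chromanet_degenerate_error")
  allpos <- rowSums(kept == 0) == 0
  cn_assert(any(allpos),
            "no gene with all-positive counts; size-factor reference undefined",
            "chromanet_degenerate_error")
  loggeo <- rowMeans(log(kept[allpos, , drop = FALSE]))
  sf <- apply(kept[allpos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
  if (!is.null(gene_chrom)) gene_chrom <- gene_chrom[rownames(kept)]
  structure(
    list(counts = kept, norm = sweep(kept, 2, sf, "/"),
         size_factors = sf, condition = condition, gene_chrom = gene_chrom,
         ledger = list(n_filtered = sum(low), n_kept = nrow(kept))),
    class = "ExpressionMatrix"
  )
}

# internal: equal-frequency rank discretization into nbins levels
discretize_rank <- function(x, nbins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * nbins / length(x)))
}

# internal: default grid size for the plug-in MI estimator
mi_grid_size <- function(n) max(2L, as.integer(floor(sqrt(n / 5))))

#' Mutual information between two expression profiles
#'
#' Plug-in MI (in nats) on a square equal-frequency grid of rank-transformed
#' values: `sum p * log(p / (p_x p_y))` over the joint contingency table, with
#' grid size `floor(sqrt(n / 5))` (minimum 2) and the Miller-Madow bias
#' correction `(B - 1)^2 / (2n)` subtracted (the plug-in estimator's
#' first-order positive bias under independence). Rank-based, hence invariant
#' under strictly monotone transforms of either argument, and symmetric.
#'
#' @param x,y numeric vectors of equal length >= 10.
#' @return MI in nats (>= 0). A constant input yields 0 with attribute
#'   `degenerate = TRUE`.
#' @export
estimate_mi <- function(x, y) {
  cn_assert(length(x) == length(y) && length(x) >= 10,
            "need equal-length vectors of >= 10 samples")
  if (max(x) == min(x) || max(y) == min(y)) {
    return(structure(0, degenerate = TRUE))
  }
  nb <- mi_grid_size(length(x))
  tab <- table(discretize_rank(x, nb), discretize_rank(y, nb))
  p <- tab / length(x)
  px <- rowSums(p); py <- colSums(p)
  term <- p * log(p / outer(px, py))
  term[p == 0] <- 0
  max(sum(term) - (nb - 1)^2 / (2 * length(x)), 0)
}

# internal: MI for all gene pairs of a matrix (genes x samples) on one shared
# grid; returns a genes x genes symmetric matrix. Identical discretization to
# estimate_mi, vectorized through per-level indicator cross-products.
mi_matrix <- function(mat, nbins = mi_grid_size(ncol(mat))) {
  n <- ncol(mat)
  disc <- t(apply(mat, 1, discretize_rank, nbins = nbins))
  if (nrow(mat) == 1) disc <- matrix(disc, nrow = 1)
  ind <- lapply(seq_len(nbins), function(a) (disc == a) * 1)
  marg <- vapply(ind, rowSums, numeric(nrow(mat)))
  mi <- matrix(0, nrow(mat), nrow(mat))
  for (a in seq_len(nbins)) {
    for (b in seq_len(nbins)) {
      nab <- tcrossprod(ind[[a]], ind[[b]])
      expab <- outer(marg[, a], marg[, b]) / n
      term <- (nab / n) * log(nab / expab)
      term[nab == 0] <- 0
      mi <- mi + term
    }
  }
  dimnames(mi) <- list(rownames(mat), rownames(mat))
  pmax(mi - (nbins - 1)^2 / (2 * n), 0)
}

#' Null-based MI significance threshold
#'
#' Estimates the MI value exceeded with probability `pvalue` under
#' independence: draws `n_null` random gene pairs, permutes one member's
#' samples, fits an exponential tail (linear fit of log empirical survival) to
#' the top 5% of the null MIs, and solves for the MI at tail probability
#' `pvalue`. The exponential tail allows thresholds far beyond the largest
#' simulated null value (e.g. p = 1e-8 from 1e4 draws).
#'
#' @param mat normalized expression matrix (genes x samples).
#' @param pvalue target tail probability.
#' @param n_null number of null pairs to simulate (>= 1000).
#' @param seed RNG seed; the estimate is deterministic given the seed.
#' @return MI threshold in nats, with attributes `fit` (intercept, slope) and
#'   `null_quantile95`.
#' @export
estimate_mi_threshold <- function(mat, pvalue = 1e-8, n_null = 10000L,
                                  seed = 1L) {
  cn_assert(pvalue > 0 && pvalue < 1, "pvalue in (0,1)",
            "chromanet_domain_error")
  cn_assert(n_null >= 1000, "n_null too small for a tail fit")
  cn_assert(nrow(mat) >= 2, "need at least two genes")
  set.seed(seed)
  n <- ncol(mat)
  g1 <- sample.int(nrow(mat), n_null, replace = TRUE)
  g2 <- sample.int(nrow(mat), n_null, replace = TRUE)
  null_mi <- vapply(seq_len(n_null), function(k) {
    estimate_mi(mat[g1[k], ], mat[g2[k], sample.int(n)])
  }, numeric(1))
  cn_assert(max(null_mi) > 0, "degenerate null (all MI zero)",
            "chromanet_degenerate_error")
  xs <- sort(null_mi)
  m <- ceiling(0.05 * n_null)
  idx <- seq(n_null - m + 1L, n_null - 1L)  # top 5%, excluding the maximum
  surv <- (n_null - idx) / n_null
  fit <- stats::lm(log(surv) ~ xs[idx])
  a <- stats::coef(fit)[1]; slope <- stats::coef(fit)[2]
  cn_assert(slope < 0, "null tail not decreasing; cannot extrapolate",
            "chromanet_degenerate_error")
  structure(as.numeric((log(pvalue) - a) / slope),
            fit = c(intercept = unname(a), slope = unname(slope)),
            null_quantile95 = as.numeric(stats::quantile(null_mi, 0.95)))
}

#' Bootstrap consensus co-expression network
#'
#' Infers `B` MI networks from bootstrap resamples of samples (columns, with
#' replacement): in each resample, every intra-chromosomal gene pair with MI
#' at or above `mi_threshold` forms an edge. Each pair's support `k` (number
#' of bootstrap networks containing it) is tested against a Poisson null with
#' rate `lambda` = mean support over all candidate pairs; pairs with
#' `P(X >= k) < alpha / m` (Bonferroni over the `m` candidate pairs) are
#' retained. Edge MI is the median over supporting bootstraps.
#'
#' @param mat normalized expression matrix (genes x samples) for one
#'   chromosome's genes.
#' @param B number of bootstrap networks.
#' @param mi_threshold MI significance threshold (from
#'   [estimate_mi_threshold()]).
#' @param alpha family-wise level of the consensus test.
#' @param seed RNG seed.
#' @return an `MINetwork`: data.frame with `gene_a`, `gene_b`, `mi`,
#'   `support`, `pvalue`; attributes `lambda`, `B`, `mi_threshold`,
#'   `n_candidates`.
#' @export
bootstrap_consensus_network <- function(mat, B = 100L, mi_threshold,
                                        alpha = 0.05, seed = 1L) {
  cn_assert(B >= 2, "B must be >= 2")
  G <- nrow(mat)
  if (G < 2) {
    warning("fewer than two genes; empty network")
    return(empty_mi_network(mi_threshold, B))
  }
  set.seed(seed)
  ut <- which(upper.tri(matrix(0, G, G)))
  m <- length(ut)
  support <- integer(m)
  mi_sum <- vector("list", B)
  for (bb in seq_len(B)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    mi <- mi_matrix(mat[, cols, drop = FALSE])[ut]
    hit <- mi >= mi_threshold
    support <- support + hit
    mi_sum[[bb]] <- ifelse(hit, mi, NA_real_)
  }
  lambda <- sum(support) / m
  pvals <- stats::ppois(support - 1, lambda, lower.tail = FALSE)
  keep <- pvals < alpha / m & support > 0
  ij <- arrayInd(ut[keep], c(G, G))
  mi_all <- do.call(cbind, mi_sum)  # m x B, NA where below threshold
  med <- apply(mi_all[keep, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  out <- data.frame(
    gene_a = rownames(mat)[ij[, 1]], gene_b = rownames(mat)[ij[, 2]],
    mi = as.numeric(med), support = support[keep], pvalue = pvals[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, lambda = lambda, B = B, mi_threshold = mi_threshold,
            n_candidates = m, class = c("MINetwork", "data.frame"))
}

empty_mi_network <- function(mi_threshold = NA_real_, B = NA_integer_) {
  structure(
    data.frame(gene_a = character(), gene_b = character(), mi = numeric(),
               support = integer(), pvalue = numeric(),
               stringsAsFactors = FALSE),
    lambda = NA_real_, B = B, mi_threshold = mi_threshold, n_candidates = 0L,
    class = c("MINetwork", "data.frame"))
}
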