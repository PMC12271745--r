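#' Support of the noncentral hypergeometric null
#'
#' The null for a bin pair's contact count is a Fisher noncentral
#' hypergeometric distribution with population `2n` (twice the chromosome's
#' total contact count), `n_i` success states, `n_j` draws and odds ratio
#' `omega`; the count can range over `[max(0, n_j - (2n - n_i)), min(n_i,
#' n_j)]`.
#'
#' @param n total contact count of the chromosome.
#' @param ni,nj marginal contact counts of the two bins.
#' @return integer-valued vector `c(kmin, kmax)`.
#' @export
nchg_support <- function(n, ni, nj) {
  cn_assert(n > 0 && ni >= 0 && nj >= 0 && ni <= 2 * n && nj <= 2 * n,
            "invalid NCHG parameters", "chromanet_domain_error")
  c(max(0, nj - (2 * n - ni)), min(ni, nj))
}

#' Noncentral hypergeometric probability mass
#'
#' Probability of observing `k` contacts between two loci given the
#' chromosome total `n`, the loci marginals `n_i`, `n_j`, and the
#' distance-dependent odds ratio `omega`. Computed in log-space with
#' log-sum-exp normalization over the full support; with `omega = 1` this is
#' the central hypergeometric pmf with population `2n`.
#'
#' @param k observed contact count (vectorized).
#' @param n,ni,nj,omega null parameters (scalars).
#' @return probabilities in `[0, 1]`; 0 outside the support.
#' @export
nchg_pmf <- function(k, n, ni, nj, omega) {
  cn_assert(omega > 0, "omega must be > 0", "chromanet_domain_error")
  sup <- nchg_support(n, ni, nj)
  ks <- seq(sup[1], sup[2])
  cn_assert(length(ks) <= 1e6, "NCHG support exceeds 1e6 states",
            "chromanet_domain_error")
  lw <- lchoose(ni, ks) + lchoose(2 * n - ni, nj - ks) + ks * log(omega)
  mx <- max(lw)
  p <- exp(lw - mx) / sum(exp(lw - mx))
  out <- numeric(length(k))
  inside <- k >= sup[1] & k <= sup[2] & k == round(k)
  out[inside] <- p[k[inside] - sup[1] + 1]
  out
}

#' Upper-tail NCHG p-value
#'
#' Survival probability `P(X >= k)` of the noncentral hypergeometric null —
#' the significance test for an observed contact count. Vectorized over all
#' arguments (recycled); computation is in log-space with full-support
#' normalization.
#'
#' @param k observed counts.
#' @param n,ni,nj,omega null parameters.
#' @return p-values in `(0, 1]` (0 only when `k` exceeds the support maximum).
#' @export
nchg_pvalue <- function(k, n, ni, nj, omega) {
  m <- max(length(k), length(n), length(ni), length(nj), length(omega))
  .nchg_tail_cpp(rep_len(as.numeric(k), m), rep_len(as.numeric(n), m),
                 rep_len(as.numeric(ni), m), rep_len(as.numeric(nj), m),
                 rep_len(as.numeric(omega), m))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation;
#' order-preserving and element-wise `q >= p`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  cn_assert(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]",
            "chromanet_domain_error")
  stats::p.adjust(pvalues, method = "BH")
}

#' Distance-dependent odds ratio for the NCHG null
#'
#' Odds of the bias-adjusted decay probability at the pair's distance relative
#' to the odds of the global mean per-pair contact probability:
#' `omega = odds(clamp(f(d) * b_i * b_j)) / odds(p_bar)`. Equals 1 when the
#' decay is flat at the global mean and biases are 1; non-increasing in
#' distance for fixed biases.
#'
#' @param distance genomic distance(s) in bp (midpoint to midpoint).
#' @param decay a fitted [fit_decay_model()] object.
#' @param b_i,b_j per-bin visibility biases.
#' @param eps clamp for the adjusted probability, kept inside `(eps, 1 - eps)`.
#' @return odds ratio(s) `> 0`.
#' @export
expected_odds <- function(distance, decay, b_i = 1, b_j = 1, eps = 1e-12) {
  cn_assert(inherits(decay, "DecayModel"), "decay must be a DecayModel")
  p_hat <- pmin(pmax(decay_evaluate(decay, distance) * b_i * b_j, eps), 1 - eps)
  p_bar <- min(max(decay$baseline, eps), 1 - eps)
  (p_hat / (1 - p_hat)) / (p_bar / (1 - p_bar))
}
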