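#' ICE matrix balancing
#'
#' Iterative correction of a contact map under the equal-visibility
#' assumption: finds multiplicative per-bin biases `b` such that the corrected
#' matrix with entries `n_ij / (b_i * b_j)` has equal row sums across unmasked
#' bins. Bins with zero marginal are masked before balancing and get `NA`
#' biases. Biases are normalized to mean 1 over unmasked bins.
#'
#' @param map a [contact_map()].
#' @param max_iter maximum number of correction sweeps.
#' @param tol convergence tolerance: coefficient of variation of unmasked
#'   corrected row sums.
#' @return a list with `map` (balanced `ContactMap`, corrected counts and the
#'   bias vector attached), `bias`, `iterations`, `cv`.
#' @export
ice_balance <- function(map, max_iter = 200L, tol = 1e-6) {
  cn_assert(inherits(map, "ContactMap"), "map must be a ContactMap")
  cn_assert(map$total > 0, "all-zero matrix cannot be balanced",
            "chromanet_degenerate_error")
  m <- contact_map_dense(map)
  masked <- rowSums(m) == 0
  b <- rep(1, map$n_bins)
  cv <- Inf
  it <- 0L
  pop_cv <- function(x) {
    mu <- mean(x)
    sqrt(mean((x - mu)^2)) / mu
  }
  while (it < max_iter) {
    it <- it + 1L
    cm <- m / outer(b, b)
    s <- rowSums(cm[, !masked, drop = FALSE])
    su <- s[!masked]
    cv <- pop_cv(su)
    if (cv < tol) break
    b[!masked] <- b[!masked] * su / mean(su)
  }
  if (cv >= tol) {
    cn_stop(sprintf("ICE did not converge in %d iterations (CV %.3g)",
                    max_iter, cv), "chromanet_convergence_error")
  }
  # rescale to mean-1 biases over unmasked bins (row sums stay equal)
  b[!masked] <- b[!masked] / mean(b[!masked])
  b[masked] <- NA_real_
  bf <- ifelse(masked, 1, b)
  corrected <- m / outer(bf, bf)
  corrected[masked, ] <- 0
  corrected[, masked] <- 0
  out <- contact_map_from_dense(map$chrom, corrected, map$resolution, bias = b)
  list(map = out, bias = b, iterations = it, cv = cv)
}
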