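#' Filter a contact map before significance testing
#'
#' Removes, in order and each counted on the remainder: (1) pairs touching any
#' bin overlapping a blacklist interval (any-overlap rule), (2) pairs touching
#' a centromere-overlapping bin, (3) self-interactions (diagonal pairs),
#' (4) pairs where either bin's visibility bias falls outside `bounds`
#' (bins with `NA` bias — masked during balancing — are also removed here).
#'
#' @param map a [contact_map()].
#' @param blacklist,centromeres `RegionSet`s (may be `NULL` or empty).
#' @param bias per-bin bias vector aligned to the map's bins, or `NULL` to
#'   skip the bias filter.
#' @param bounds admissible bias range, default `c(0.5, 2)`.
#' @return list with `map` (filtered `ContactMap`, excluded bins recorded in
#'   the `excluded_bins` attribute) and `ledger` (named removal counts).
#' @export
apply_filters <- function(map, blacklist = NULL, centromeres = NULL,
                          bias = NULL, bounds = c(0.5, 2)) {
  cn_assert(inherits(map, "ContactMap"), "map must be a ContactMap")
  if (!is.null(bias)) {
    cn_assert(length(bias) == map$n_bins, "bias vector length mismatch")
  }
  starts <- (seq_len(map$n_bins) - 1L) * map$resolution
  bins_gr <- GenomicRanges::GRanges(
    seqnames = map$chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = starts + map$resolution))
  region_bins <- function(regions) {
    flag <- rep(FALSE, map$n_bins)
    if (is.null(regions) || nrow(regions) == 0) return(flag)
    hits <- GenomicRanges::findOverlaps(bins_gr, regions_as_granges(regions))
    flag[unique(S4Vectors::queryHits(hits))] <- TRUE
    flag
  }
  bl_bins <- region_bins(blacklist)
  ce_bins <- region_bins(centromeres)
  bias_bins <- rep(FALSE, map$n_bins)
  if (!is.null(bias)) {
    bias_bins <- is.na(bias) | bias < bounds[1] | bias > bounds[2]
  }
  ent <- map$entries
  ledger <- c(blacklist = 0L, centromere = 0L, self_interaction = 0L,
              bias_bounds = 0L)
  drop_pairs <- function(ent, bad, name) {
    hit <- bad[ent$bin_i + 1L] | bad[ent$bin_j + 1L]
    ledger[[name]] <<- sum(hit)
    ent[!hit, , drop = FALSE]
  }
  ent <- drop_pairs(ent, bl_bins, "blacklist")
  ent <- drop_pairs(ent, ce_bins, "centromere")
  diag_hit <- ent$bin_i == ent$bin_j
  ledger[["self_interaction"]] <- sum(diag_hit)
  ent <- ent[!diag_hit, , drop = FALSE]
  ent <- drop_pairs(ent, bias_bins, "bias_bounds")
  out <- contact_map(map$chrom, ent, map$n_bins, map$resolution, bias = map$bias)
  attr(out, "excluded_bins") <- bl_bins | ce_bins | bias_bins
  list(map = out, ledger = as.list(ledger))
}

#' Call significant intrachromosomal interactions
#'
#' For every observed candidate pair surviving the filters, computes the
#' distance-dependent odds ratio from the fitted decay model (with a
#' positional visibility correction for finite-chromosome edge effects), the
#' noncentral hypergeometric upper-tail p-value against the chromosome's
#' totals and marginals, and Benjamini-Hochberg q-values over the
#' chromosome's tested pairs. Technical per-bin biases do not enter the odds
#' ratio: the marginals conditioning the null already carry them, so they
#' cancel. Zero-count pairs have p = 1 by construction and are not
#' enumerated. Deterministic.
#'
#' @param map a [contact_map()] of raw counts.
#' @param blacklist,centromeres optional `RegionSet`s.
#' @param bias optional per-bin bias vector (used for the bias-bounds
#'   filter).
#' @param bias_bounds admissible bias range.
#' @param metabin_size pairs per metabin for the decay fit.
#' @param fdr_level BH FDR retention level (rows with `q <= fdr_level` kept).
#' @param decay optional pre-fitted `DecayModel`; fitted on the filtered map
#'   when `NULL`.
#' @return a `SignificanceResult`: list with `edges` (retained edge table),
#'   `tested` (all tested pairs with omega, p, q), `decay`, `ledger`,
#'   `fdr_level`.
#' @export
call_significant_interactions <- function(map, blacklist = NULL,
                                          centromeres = NULL, bias = NULL,
                                          bias_bounds = c(0.5, 2),
                                          metabin_size = 200L,
                                          fdr_level = 0.05,
                                          decay = NULL) {
  flt <- apply_filters(map, blacklist, centromeres, bias, bias_bounds)
  fmap <- flt$map
  if (is.null(decay)) decay <- fit_decay_model(fmap, metabin_size)
  ent <- fmap$entries
  cn_assert(nrow(ent) > 0, "no candidate pairs survive the filters",
            "chromanet_degenerate_error")
  dist <- (ent$bin_j - ent$bin_i) * fmap$resolution
  # Positional visibility correction. The marginals n_i entering the NCHG
  # already carry each bin's technical bias, so the odds ratio must not
  # multiply it in again (it cancels); what the marginals also carry is the
  # finite-chromosome positional factor s_i = sum_j f(d_ij) — edge bins have
  # fewer close neighbours, hence smaller marginals for the same visibility.
  # Passing b_i = sqrt(2 p_bar) / s_i to the odds formula makes the null mean
  # (n_i n_j / 2n) * omega match the decay expectation at every position.
  excluded <- attr(fmap, "excluded_bins")
  kept_bins <- which(!excluded) - 1L
  fd <- c(NA, decay_evaluate(decay, seq_len(fmap$n_bins - 1L) * fmap$resolution))
  s <- vapply(kept_bins, function(i) {
    d <- abs(kept_bins - i)
    sum(fd[d[d > 0] + 1L])
  }, numeric(1))
  s_of <- rep(NA_real_, fmap$n_bins)
  s_of[kept_bins + 1L] <- s
  pos_fac <- sqrt(2 * decay$baseline) / s_of
  omega_lin <- expected_odds(dist, decay, pos_fac[ent$bin_i + 1L],
                             pos_fac[ent$bin_j + 1L])
  ni <- fmap$marginals[ent$bin_i + 1L]
  nj <- fmap$marginals[ent$bin_j + 1L]
  # Mean-matching: the linear-regime expected count (n_i n_j / 2n) * omega is
  # accurate, but at short distances it is a non-negligible fraction of the
  # marginals, where the Fisher-NCHG mean falls below n_i n_j omega / 2n.
  # Use the odds ratio of the expected 2x2 table, which makes the null mean
  # equal the decay expectation exactly.
  n2 <- 2 * fmap$total
  mu <- pmin(ni * nj / n2 * omega_lin, 0.99 * pmin(ni, nj))
  omega <- mu * (n2 - ni - nj + mu) / ((ni - mu) * (nj - mu))
  p <- nchg_pvalue(ent$count, fmap$total, ni, nj, omega)
  q <- bh_adjust(p)
  tested <- data.frame(chrom = fmap$chrom, bin_i = ent$bin_i,
                       bin_j = ent$bin_j, count = ent$count,
                       distance_bp = dist, omega = omega, pvalue = p,
                       qvalue = q, zscore = NA_real_,
                       edge_type = NA_character_, stringsAsFactors = FALSE)
  structure(
    list(edges = tested[tested$qvalue <= fdr_level, , drop = FALSE],
         tested = tested, decay = decay, ledger = flt$ledger,
         fdr_level = fdr_level),
    class = "SignificanceResult"
  )
}

#' @export
print.SignificanceResult <- function(x, ...) {
  cat(sprintf("SignificanceResult: %d/%d pairs at q <= %g (filters removed: %s)\n",
              nrow(x$edges), nrow(x$tested), x$fdr_level,
              paste(names(x$ledger), unlist(x$ledger), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
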