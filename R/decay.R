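#' Fit the monotone distance-decay null model
#'
#' Groups candidate bin pairs (all unordered off-diagonal pairs among the
#' map's non-excluded bins, zero-count pairs included) into consecutive
#' metabins of `metabin_size` pairs ordered by genomic distance, computes each
#' metabin's mean distance and mean per-pair contact probability
#' (`count / total`), enforces monotone non-increase by isotonic regression on
#' the metabin means, and interpolates the adjusted knots with a monotone
#' cubic spline. Distances outside the knot range evaluate at the boundary
#' knots.
#'
#' @param map a [contact_map()], typically after [apply_filters()].
#' @param metabin_size distance-ordered pairs per metabin (>= 2).
#' @return a `DecayModel` with fields `knots` (distance, prob), `baseline`
#'   (global mean per-pair contact probability), `metabin_size`, `n_pairs`.
#' @export
fit_decay_model <- function(map, metabin_size = 200L) {
  cn_assert(inherits(map, "ContactMap"), "map must be a ContactMap")
  cn_assert(metabin_size >= 2, "metabin_size must be >= 2")
  excluded <- attr(map, "excluded_bins")
  if (is.null(excluded)) excluded <- rep(FALSE, map$n_bins)
  keep <- which(!excluded) - 1L
  nb <- length(keep)
  cn_assert(nb >= 2, "fewer than two usable bins", "chromanet_degenerate_error")
  # enumerate all candidate pairs among kept bins (desk scale: O(nb^2))
  pair_i <- rep(keep, times = rev(seq_len(nb) - 1L))
  pair_j <- unlist(lapply(seq_len(nb - 1L), function(a) keep[(a + 1L):nb]),
                   use.names = FALSE)
  cn_assert(length(pair_i) >= metabin_size,
            "fewer candidate pairs than one metabin",
            "chromanet_degenerate_error")
  counts <- numeric(length(pair_i))
  ent <- map$entries
  ent <- ent[ent$bin_i != ent$bin_j, , drop = FALSE]
  key_all <- pair_i * map$n_bins + pair_j
  key_ent <- ent$bin_i * map$n_bins + ent$bin_j
  hit <- match(key_ent, key_all)
  counts[hit[!is.na(hit)]] <- ent$count[!is.na(hit)]
  dist <- (pair_j - pair_i) * map$resolution
  ord <- order(dist)
  dist <- dist[ord]
  counts <- counts[ord]
  grp <- (seq_along(dist) - 1L) %/% metabin_size
  md <- tapply(dist, grp, mean)
  mp <- tapply(counts, grp, mean) / map$total
  # isotonic non-increasing fit of metabin means
  iso <- stats::isoreg(seq_along(mp), -as.numeric(mp))
  y <- -iso$yf
  x <- as.numeric(md)
  # collapse duplicate knot distances (possible when one distance spans metabins)
  yc <- tapply(y, x, mean)
  xs <- as.numeric(names(yc))
  ys <- as.numeric(yc)
  ord2 <- order(xs)
  xs <- xs[ord2]; ys <- ys[ord2]
  ys <- rev(cummax(rev(ys)))  # re-assert monotone non-increase after collapsing
  floor_p <- 1e-15
  ys <- pmin(pmax(ys, floor_p), 1 - 1e-12)
  if (length(xs) >= 3 && any(diff(ys) != 0)) {
    fun <- tryCatch(stats::splinefun(xs, ys, method = "hyman"),
                    error = function(e) stats::approxfun(xs, ys, rule = 2))
  } else if (length(xs) >= 2) {
    fun <- stats::approxfun(xs, ys, rule = 2)
  } else {
    fun <- function(d) rep(ys[1], length(d))
  }
  structure(
    list(knots = data.frame(distance = xs, prob = ys),
         fun = fun,
         baseline = sum(counts) / (as.numeric(length(counts)) * map$total),
         metabin_size = as.integer(metabin_size),
         n_pairs = length(counts), total = map$total,
         range = c(min(xs), max(xs)), floor = floor_p),
    class = "DecayModel"
  )
}

#' Evaluate the decay model at genomic distances
#'
#' @param decay a `DecayModel`.
#' @param distance distances in bp; clamped to the knot range.
#' @return per-pair contact probabilities in `(0, 1)`.
#' @export
decay_evaluate <- function(decay, distance) {
  cn_assert(inherits(decay, "DecayModel"), "decay must be a DecayModel")
  d <- pmin(pmax(distance, decay$range[1]), decay$range[2])
  pmin(pmax(decay$fun(d), decay$floor), 1 - 1e-12)
}

#' @export
print.DecayModel <- function(x, ...) {
  cat(sprintf("DecayModel: %d knots over [%g, %g] bp | baseline %.3g | metabin %d pairs\n",
              nrow(x$knots), x$range[1], x$range[2], x$baseline, x$metabin_size))
  invisible(x)
}
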