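jaccard_of_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) {
    message("jaccard: both sets empty; returning 1 by convention")
    return(1)
  }
  length(intersect(a, b)) / u
}

edge_keys <- function(net) {
  if (igraph::ecount(net) == 0) return(character())
  el <- igraph::as_edgelist(net, names = TRUE)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
}

#' Jaccard similarity between two condition networks
#'
#' Compares the node-id sets, the unordered endpoint-pair edge sets, or the
#' edge sets within each edge-type class. Edge identity is the endpoint pair
#' only; attributes are ignored. Two empty sets compare as 1 (identical), with
#' a message.
#'
#' @param netA,netB networks from [build_chromosome_network()] on the same
#'   chromosome and bin grid.
#' @param mode `"nodes"`, `"edges"` or `"edge_type"` (stratified).
#' @return a single value, or for `"edge_type"` a named vector over the edge
#'   classes present in either network.
#' @export
jaccard_similarity <- function(netA, netB, mode = c("nodes", "edges",
                                                    "edge_type")) {
  mode <- match.arg(mode)
  cn_assert(identical(igraph::graph_attr(netA, "chrom"),
                      igraph::graph_attr(netB, "chrom")) &&
              identical(igraph::graph_attr(netA, "resolution"),
                        igraph::graph_attr(netB, "resolution")),
            "networks must share chromosome and resolution")
  if (mode == "nodes") {
    return(jaccard_of_sets(igraph::V(netA)$name, igraph::V(netB)$name))
  }
  ka <- edge_keys(netA)
  kb <- edge_keys(netB)
  if (mode == "edges") return(jaccard_of_sets(ka, kb))
  ta <- if (igraph::ecount(netA) > 0) igraph::edge_attr(netA, "edge_type") else character()
  tb <- if (igraph::ecount(netB) > 0) igraph::edge_attr(netB, "edge_type") else character()
  types <- sort(unique(c(ta, tb)))
  vapply(types, function(tt) jaccard_of_sets(ka[ta == tt], kb[tb == tt]),
         numeric(1))
}

#' Edge-count log2 fold change between conditions
#'
#' @param netA,netB reference and contrast networks.
#' @return `log2(|E_B| / |E_A|)`.
#' @export
interaction_count_logfc <- function(netA, netB) {
  ea <- igraph::ecount(netA)
  cn_assert(ea > 0, "reference network has no edges; logFC undefined",
            "chromanet_degenerate_error")
  log2(igraph::ecount(netB) / ea)
}

#' Contact-frequency distance-decay curve
#'
#' Mean balanced count per genomic-distance bin, for decay plots and
#' condition comparison. Distances are pooled into log-spaced bins (the
#' conventional display for power-law decay) and all bin pairs in each
#' distance bin are averaged, zero-count pairs included.
#'
#' @param map a balanced [contact_map()].
#' @param n_breaks number of log-spaced distance bins.
#' @return data.frame with `distance_bp` (geometric mid of the bin),
#'   `mean_count` and `n_pairs`.
#' @export
decay_curve <- function(map, n_breaks = 30) {
  m <- contact_map_dense(map)
  nb <- map$n_bins
  vals <- unlist(lapply(seq_len(nb - 1), function(d) {
    idx <- seq_len(nb - d)
    m[cbind(idx, idx + d)]
  }), use.names = FALSE)
  d_all <- rep(seq_len(nb - 1), times = nb - seq_len(nb - 1))
  breaks <- unique(round(exp(seq(log(1), log(nb - 1),
                                 length.out = n_breaks + 1))))
  grp <- cut(d_all, breaks = c(0, breaks), labels = FALSE)
  data.frame(
    distance_bp = as.numeric(tapply(d_all, grp, function(x)
      exp(mean(log(x))))) * map$resolution,
    mean_count = as.numeric(tapply(vals, grp, mean)),
    n_pairs = as.integer(tapply(vals, grp, length))
  )
}

#' Entrywise log2 fold-change matrix
#'
#' `log2((B + eps) / (A + eps))` over the union support of two maps on the
#' same grid.
#'
#' @param mapA,mapB contact maps on the same bin grid.
#' @param pseudocount positive stabilizer `eps`.
#' @return data.frame `bin_i`, `bin_j`, `log2fc` over the union of nonzero
#'   pairs.
#' @export
logfc_matrix <- function(mapA, mapB, pseudocount = 1) {
  cn_assert(pseudocount > 0, "pseudocount must be positive")
  cn_assert(mapA$n_bins == mapB$n_bins, "maps on different grids")
  key <- function(m) m$entries$bin_i * m$n_bins + m$entries$bin_j
  ka <- key(mapA); kb <- key(mapB)
  ku <- sort(unique(c(ka, kb)))
  a <- numeric(length(ku)); b <- numeric(length(ku))
  a[match(ka, ku)] <- mapA$entries$count
  b[match(kb, ku)] <- mapB$entries$count
  data.frame(bin_i = as.integer(ku %/% mapA$n_bins),
             bin_j = as.integer(ku %% mapA$n_bins),
             log2fc = log2((b + pseudocount) / (a + pseudocount)))
}

#' Per-node degree and Z-weighted degree
#'
#' Degree is the incident-edge count; the Z-weighted degree is the sum of the
#' absolute contact-count Z-scores over a node's incident edges, a
#' strength-aware connectivity measure.
#'
#' @param net a network with a `zscore` edge attribute.
#' @return data.frame with `node`, `degree`, `z_weighted_degree` (isolated
#'   nodes score 0).
#' @export
node_metrics <- function(net) {
  if (igraph::ecount(net) > 0) {
    cn_assert(!is.null(igraph::edge_attr(net, "zscore")) &&
                !anyNA(igraph::edge_attr(net, "zscore")),
              "zscore edge attribute missing")
  }
  deg <- igraph::degree(net)
  zw <- igraph::strength(
    net, weights = if (igraph::ecount(net) > 0)
      abs(igraph::edge_attr(net, "zscore")) else NULL)
  data.frame(node = igraph::V(net)$name, degree = as.integer(deg),
             z_weighted_degree = as.numeric(zw), stringsAsFactors = FALSE)
}

#' Per-node neighbourhood dissimilarity between conditions
#'
#' For each node present in both networks, `DI = 1 -` Jaccard similarity of
#' its neighbour sets, so 0 means fully preserved wiring and 1 full rewiring.
#' Nodes absent from one network are excluded and counted.
#'
#' @param netA,netB condition networks on the same grid.
#' @return data.frame of records ranked ascending by `DI` (ties by node id),
#'   columns `node`, `DI`, `rank`, `n_neighbors_A`, `n_neighbors_B`; attribute
#'   `n_excluded`.
#' @export
node_dissimilarity_profile <- function(netA, netB) {
  shared <- intersect(igraph::V(netA)$name, igraph::V(netB)$name)
  cn_assert(length(shared) > 0, "no shared nodes",
            "chromanet_degenerate_error")
  na_list <- igraph::adjacent_vertices(netA, shared)
  nb_list <- igraph::adjacent_vertices(netB, shared)
  di <- vapply(seq_along(shared), function(i) {
    1 - jaccard_of_sets(names(na_list[[i]]), names(nb_list[[i]]))
  }, numeric(1))
  out <- data.frame(
    node = shared, DI = di,
    n_neighbors_A = lengths(na_list), n_neighbors_B = lengths(nb_list),
    stringsAsFactors = FALSE)
  out <- out[order(out$DI, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  n_excl <- length(union(igraph::V(netA)$name, igraph::V(netB)$name)) -
    length(shared)
  attr(out, "n_excluded") <- n_excl
  out[, c("node", "DI", "rank", "n_neighbors_A", "n_neighbors_B")]
}

#' Kneedle elbow detection on a ranked curve
#'
#' Normalizes rank and value to `[0, 1]` and locates the maximum of the
#' difference curve `x_norm - y_norm` (the orientation for convex increasing
#' profiles, which stay below the diagonal until they turn up) — the point of
#' maximum curvature of a ranked, ascending profile. No smoothing: the inputs
#' here are monotone ranked curves, so the exact argmax is deterministic.
#' Ties resolve to the smallest index.
#'
#' @param values numeric vector, ranked ascending.
#' @return list with `threshold` (value at the elbow) and `index`.
#' @export
kneedle_threshold <- function(values) {
  cn_assert(length(values) >= 3, "need at least 3 values",
            "chromanet_degenerate_error")
  cn_assert(max(values) > min(values), "all values equal; no elbow",
            "chromanet_degenerate_error")
  x <- (seq_along(values) - 1) / (length(values) - 1)
  y <- (values - min(values)) / (max(values) - min(values))
  delta <- x - y
  if (max(abs(delta)) < 1e-10) {
    cn_stop("difference curve identically zero (linear ramp); no elbow",
            "chromanet_degenerate_error")
  }
  idx <- which.max(delta)
  list(threshold = values[idx], index = idx)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of overlap between a query gene set and
#' each collection set (both intersected with the universe), with
#' Benjamini-Hochberg adjustment across the tested sets.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param universe background gene ids.
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha significance level on the adjusted p-value.
#' @return data.frame with `set`, `overlap`, `set_size`, `universe_size`,
#'   `query_size`, `pvalue`, `adj_pvalue`, `significant`.
#' @export
hypergeometric_enrichment <- function(query, universe, collections,
                                      alpha = 0.05) {
  cn_assert(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  cn_assert(all(query %in% universe), "query must be a subset of the universe")
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(unique(collections[[nm]]), universe)
    k <- length(intersect(query, set))
    # upper tail P(X >= k); k = 0 gives p = 1
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               universe_size = length(universe), query_size = length(query),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_pvalue <- bh_adjust(out$pvalue)
  out$significant <- out$adj_pvalue < alpha
  out[order(out$pvalue), , drop = FALSE]
}
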