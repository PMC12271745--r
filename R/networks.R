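#' Chromosome-wise Z-scores of interaction counts
#'
#' Standardizes edge interaction counts within a chromosome: `z = (count -
#' mu) / sigma` with the chromosome's own mean and population standard
#' deviation, so stronger-than-typical contacts score positive regardless of
#' chromosome-specific coverage.
#'
#' @param edges edge table with `chrom` and `count` columns.
#' @return the edge table with its `zscore` column filled.
#' @export
compute_edge_zscores <- function(edges) {
  cn_assert(nrow(edges) >= 2, "need at least two edges",
            "chromanet_degenerate_error")
  for (ch in unique(edges$chrom)) {
    idx <- edges$chrom == ch
    x <- edges$count[idx]
    cn_assert(sum(idx) >= 2, "need at least two edges per chromosome",
              "chromanet_degenerate_error")
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    cn_assert(sigma > 0, "all edge counts equal; Z-scores undefined",
              "chromanet_degenerate_error")
    edges$zscore[idx] <- (x - mu) / sigma
  }
  edges
}

node_type_order <- c("C", "R", "N")

# internal: unordered edge-type label ordered C, R, N (e.g. "C-N", "R-N")
edge_type_label <- function(ta, tb) {
  ia <- match(ta, node_type_order)
  ib <- match(tb, node_type_order)
  paste(node_type_order[pmin(ia, ib)], node_type_order[pmax(ia, ib)], sep = "-")
}

# internal: classify bins by TSS content: C if any coding TSS, else R if any
# ncRNA TSS, else N (coding precedence for mixed bins)
classify_bins <- function(n_bins, resolution, genes, chrom) {
  types <- rep("N", n_bins)
  gene_lists <- vector("list", n_bins)
  if (!is.null(genes) && nrow(genes) > 0) {
    g <- genes[genes$chrom == chrom & genes$tss >= 0 &
                 genes$tss < n_bins * resolution, , drop = FALSE]
    if (nrow(g) > 0) {
      gbin <- as.integer(g$tss %/% resolution) + 1L
      for (k in seq_len(nrow(g))) {
        gene_lists[[gbin[k]]] <- c(gene_lists[[gbin[k]]], g$gene_id[k])
        if (g$biotype[k] == "coding") {
          types[gbin[k]] <- "C"
        } else if (types[gbin[k]] == "N") {
          types[gbin[k]] <- "R"
        }
      }
    }
  }
  list(types = types, genes = gene_lists)
}

#' Build a per-chromosome chromatin-interaction network
#'
#' Retains edges with `qvalue < q_threshold` (strict) and builds an
#' undirected, unweighted igraph of 40 kb-bin nodes. Node attributes: `start`,
#' `end`, `midpoint`, `node_type` (`C` if the bin holds a coding TSS, else `R`
#' if a ncRNA TSS, else `N`; coding precedence) and `genes` (semicolon-joined
#' ids). Edge attributes: `qvalue`, `distance_bp`, `count`, `zscore`,
#' `edge_type` (endpoint types, unordered, written in C, R, N order).
#'
#' @param edges edge table with q-values and zscores.
#' @param bins a `BinTable` covering the chromosome.
#' @param genes gene records (same chromosome; others ignored).
#' @param q_threshold retention cut, default 0.001.
#' @param keep_isolated also include all non-filtered bins as isolated nodes.
#' @return an igraph with graph attributes `chrom` and `resolution`
#'   (a `ChromNetwork`).
#' @export
build_chromosome_network <- function(edges, bins, genes = NULL,
                                     q_threshold = 0.001,
                                     keep_isolated = FALSE) {
  chrom <- unique(edges$chrom)
  cn_assert(length(chrom) <= 1, "edge table spans multiple chromosomes")
  if (length(chrom) == 0) chrom <- unique(bins$chrom)[1]
  sub <- bins_for_chrom(bins, chrom)
  res <- attr(bins, "resolution")
  keep <- edges[!is.na(edges$qvalue) & edges$qvalue < q_threshold, ,
                drop = FALSE]
  cn_assert(all(keep$bin_i %in% sub$bin_id) && all(keep$bin_j %in% sub$bin_id),
            "edge references a bin not in the bin table")
  cls <- classify_bins(nrow(sub), res, genes, chrom)
  node_ids <- sort(unique(c(keep$bin_i, keep$bin_j)))
  if (keep_isolated) {
    excl <- attr(edges, "excluded_bins")
    all_ids <- sub$bin_id
    if (!is.null(excl)) all_ids <- all_ids[!excl]
    node_ids <- sort(unique(c(node_ids, all_ids)))
  }
  idx <- node_ids + 1L
  g <- igraph::make_empty_graph(n = length(node_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(node_ids))
  g <- igraph::set_vertex_attr(g, "start", value = sub$start[idx])
  g <- igraph::set_vertex_attr(g, "end", value = sub$end[idx])
  g <- igraph::set_vertex_attr(g, "midpoint", value = sub$midpoint[idx])
  g <- igraph::set_vertex_attr(g, "node_type", value = cls$types[idx])
  g <- igraph::set_vertex_attr(
    g, "genes",
    value = vapply(cls$genes[idx],
                   function(x) paste(x, collapse = ";"), ""))
  if (nrow(keep) > 0) {
    lookup <- stats::setNames(seq_along(node_ids), node_ids)
    ev <- rbind(lookup[as.character(keep$bin_i)],
                lookup[as.character(keep$bin_j)])
    g <- igraph::add_edges(g, as.vector(ev))
    g <- igraph::set_edge_attr(g, "qvalue", value = keep$qvalue)
    g <- igraph::set_edge_attr(g, "distance_bp", value = keep$distance_bp)
    g <- igraph::set_edge_attr(g, "count", value = keep$count)
    g <- igraph::set_edge_attr(g, "zscore", value = keep$zscore)
    g <- igraph::set_edge_attr(
      g, "edge_type",
      value = edge_type_label(cls$types[keep$bin_i + 1L],
                              cls$types[keep$bin_j + 1L]))
  }
  g <- igraph::set_graph_attr(g, "chrom", chrom)
  g <- igraph::set_graph_attr(g, "resolution", res)
  g
}

#' Summary census of a chromatin network
#'
#' @param net a network from [build_chromosome_network()].
#' @return list with `n_nodes`, `n_edges`, `node_type_counts`,
#'   `edge_type_counts`, `degree` (named degree sequence).
#' @export
network_census <- function(net) {
  nt <- igraph::vertex_attr(net, "node_type")
  et <- if (igraph::ecount(net) > 0) igraph::edge_attr(net, "edge_type") else character()
  list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    node_type_counts = vapply(node_type_order,
                              function(t) sum(nt == t), integer(1)),
    edge_type_counts = table(factor(et, levels = c("C-C", "C-R", "C-N",
                                                   "R-R", "R-N", "N-N"))),
    degree = igraph::degree(net)
  )
}
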