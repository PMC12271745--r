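#' Map genes to their TSS-containing bins
#'
#' @param genes gene records (one chromosome).
#' @param bins a `BinTable` for that chromosome.
#' @param excluded_bins optional logical vector of filtered-out bins; genes
#'   landing there are unmapped and counted.
#' @return data.frame `gene_id`, `bin_id`; attribute `n_unmapped`.
#' @export
map_genes_to_bins <- function(genes, bins, excluded_bins = NULL) {
  chrom <- unique(genes$chrom)
  cn_assert(length(chrom) == 1, "genes must be on a single chromosome")
  sub <- bins_for_chrom(bins, chrom)
  res <- attr(bins, "resolution")
  extent <- max(sub$end)
  cn_assert(all(genes$tss >= 0 & genes$tss < extent),
            "TSS outside chromosome extent")
  bin_id <- as.integer(genes$tss %/% res)
  mapped <- rep(TRUE, length(bin_id))
  if (!is.null(excluded_bins)) mapped <- !excluded_bins[bin_id + 1L]
  out <- data.frame(gene_id = genes$gene_id[mapped], bin_id = bin_id[mapped],
                    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Assemble a two-layer chromatin/expression network
#'
#' Builds one unified, undirected, weighted graph from a Hi-C chromatin
#' network (bins) and an MI co-expression network (genes), connected by
#' interlayer edges from each mapped gene to its TSS-containing bin. Node ids
#' are namespaced by layer (`hic:<bin>`, `mi:<gene>`). Interlayer edges weigh
#' 1; Hi-C edges weigh `|zscore|` (default), raw count, or 1; MI edges weigh
#' the mutual information. Genes whose bin is not a node of the Hi-C layer
#' stay isolated from it (counted in the `n_unlinked` attribute).
#'
#' @param hic a network from [build_chromosome_network()].
#' @param mi an `MINetwork`.
#' @param gene_bin_map data.frame from [map_genes_to_bins()].
#' @param weight_scheme Hi-C edge weight: `"zscore"`, `"count"` or
#'   `"unweighted"`.
#' @return an igraph with vertex attribute `layer` (`HIC`/`MI`) and edge
#'   attributes `layer` (`hic`/`mi`/`interlayer`) and `weight`.
#' @export
assemble_multilayer <- function(hic, mi, gene_bin_map,
                                weight_scheme = c("zscore", "count",
                                                  "unweighted")) {
  weight_scheme <- match.arg(weight_scheme)
  paste_ns <- function(prefix, x) {  # paste0 maps empty input to "" — avoid
    if (length(x) == 0) character(0) else paste0(prefix, x)
  }
  hic_nodes <- paste_ns("hic:", igraph::V(hic)$name)
  gene_set <- unique(c(mi$gene_a, mi$gene_b, gene_bin_map$gene_id))
  mi_nodes <- paste_ns("mi:", gene_set)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (length(hic_nodes) > 0) {
    g <- igraph::add_vertices(g, length(hic_nodes), name = hic_nodes,
                              layer = "HIC")
  }
  if (length(mi_nodes) > 0) {
    g <- igraph::add_vertices(g, length(mi_nodes), name = mi_nodes,
                              layer = "MI")
  }
  edges <- character(0); elayer <- character(0); eweight <- numeric(0)
  if (igraph::ecount(hic) > 0) {
    el <- igraph::as_edgelist(hic, names = TRUE)
    w <- switch(weight_scheme,
                zscore = abs(igraph::edge_attr(hic, "zscore")),
                count = igraph::edge_attr(hic, "count"),
                unweighted = rep(1, nrow(el)))
    edges <- c(edges, rbind(paste0("hic:", el[, 1]), paste0("hic:", el[, 2])))
    elayer <- c(elayer, rep("hic", nrow(el)))
    eweight <- c(eweight, w)
  }
  if (nrow(mi) > 0) {
    edges <- c(edges, rbind(paste0("mi:", mi$gene_a), paste0("mi:", mi$gene_b)))
    elayer <- c(elayer, rep("mi", nrow(mi)))
    eweight <- c(eweight, mi$mi)
  }
  linked <- gene_bin_map[paste0("hic:", gene_bin_map$bin_id) %in% hic_nodes, ,
                         drop = FALSE]
  if (nrow(linked) > 0) {
    edges <- c(edges, rbind(paste0("mi:", linked$gene_id),
                            paste0("hic:", linked$bin_id)))
    elayer <- c(elayer, rep("interlayer", nrow(linked)))
    eweight <- c(eweight, rep(1, nrow(linked)))
  }
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, edges, layer = elayer, weight = eweight)
  }
  g <- igraph::set_graph_attr(g, "n_unlinked",
                              nrow(gene_bin_map) - nrow(linked))
  g
}

#' Louvain communities on a multilayer network
#'
#' Weighted Louvain modularity optimization with a fixed seed; repeated runs
#' with the same seed give identical partitions.
#'
#' @param net weighted igraph (e.g. from [assemble_multilayer()]).
#' @param seed RNG seed.
#' @param resolution Louvain resolution parameter.
#' @return a `CommunityAssignment`: list with `membership` (named integer
#'   vector), `modularity`, `seed`, `resolution`.
#' @export
detect_communities <- function(net, seed = 42L, resolution = 1) {
  cn_assert(igraph::vcount(net) > 0, "empty graph",
            "chromanet_degenerate_error")
  w <- igraph::edge_attr(net, "weight")
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, weights = w, resolution = resolution)
  structure(
    list(membership = stats::setNames(igraph::membership(cl),
                                      igraph::V(net)$name),
         modularity = max(cl$modularity), seed = seed,
         resolution = resolution),
    class = "CommunityAssignment"
  )
}

#' Align community labels between two partitions
#'
#' Greedy maximal-overlap matching on the community-by-community contingency
#' table over shared nodes: pairs are mapped in descending overlap (ties by
#' smallest labels), each community used at most once; unmatched communities
#' of the second partition keep fresh labels. Makes "changed membership"
#' invariant to label permutation.
#'
#' @param assignA,assignB `CommunityAssignment`s (or named membership
#'   vectors).
#' @return named character vector mapping B's labels onto A's label space.
#' @export
align_communities <- function(assignA, assignB) {
  a <- if (inherits(assignA, "CommunityAssignment")) assignA$membership else assignA
  b <- if (inherits(assignB, "CommunityAssignment")) assignB$membership else assignB
  shared <- intersect(names(a), names(b))
  cn_assert(length(shared) > 0, "no shared nodes",
            "chromanet_degenerate_error")
  tab <- table(A = as.character(a[shared]), B = as.character(b[shared]))
  cells <- which(tab > 0, arr.ind = TRUE)
  ord <- order(-tab[cells],
               rownames(tab)[cells[, 1]], colnames(tab)[cells[, 2]])
  cells <- cells[ord, , drop = FALSE]
  mapping <- character(0)
  used_a <- character(0)
  for (r in seq_len(nrow(cells))) {
    la <- rownames(tab)[cells[r, 1]]
    lb <- colnames(tab)[cells[r, 2]]
    if (lb %in% names(mapping) || la %in% used_a) next
    mapping[lb] <- la
    used_a <- c(used_a, la)
  }
  all_b <- unique(as.character(b))
  fresh <- setdiff(all_b, names(mapping))
  if (length(fresh) > 0) {
    mapping[fresh] <- paste0("unmatched_", fresh)
  }
  mapping
}

#' Community membership change between conditions
#'
#' Percentage of shared nodes whose (label-aligned) community differs between
#' two partitions, overall and restricted to each layer.
#'
#' @param assignA,assignB `CommunityAssignment`s or named membership vectors.
#' @param layers named character vector (node -> layer label); `NULL` for
#'   overall only.
#' @return list with `overall_pct`, `per_layer_pct` (named), `n_shared`.
#' @export
membership_change_stats <- function(assignA, assignB, layers = NULL) {
  a <- if (inherits(assignA, "CommunityAssignment")) assignA$membership else assignA
  b <- if (inherits(assignB, "CommunityAssignment")) assignB$membership else assignB
  shared <- intersect(names(a), names(b))
  cn_assert(length(shared) > 0, "no shared nodes",
            "chromanet_degenerate_error")
  mapping <- align_communities(a, b)
  b_aligned <- mapping[as.character(b[shared])]
  changed <- b_aligned != as.character(a[shared])
  per_layer <- NULL
  if (!is.null(layers)) {
    lay <- layers[shared]
    per_layer <- vapply(sort(unique(lay)), function(L) {
      100 * mean(changed[lay == L])
    }, numeric(1))
  }
  list(overall_pct = 100 * mean(changed), per_layer_pct = per_layer,
       n_shared = length(shared))
}

#' Structure-expression change analysis
#'
#' Relates chromatin-contact strength between two genes' bins to their
#' co-expression, per condition and as coupled changes. Eligible gene pairs
#' have both genes mapped to (distinct) bins, an MI value in at least one
#' condition and a Hi-C count between their bins in at least one condition.
#' A pair absent from one condition's MI network contributes MI = 0 there
#' (threshold-censored); an absent Hi-C edge contributes count 0. Log2 fold
#' changes use pseudocounts; a pair is assigned a change quadrant (`both-up`,
#' `both-down`, `hic-up-mi-down`, `hic-down-mi-up`) when both absolute fold
#' changes exceed their cutoffs, else `ns`.
#'
#' @param hicA,hicB per-condition significant-edge tables.
#' @param miA,miB per-condition `MINetwork`s.
#' @param gene_bin_map data.frame from [map_genes_to_bins()].
#' @param pseudocount Hi-C strength pseudocount.
#' @param mi_pseudocount MI pseudocount.
#' @param hic_cutoff,mi_cutoff absolute log2 fold-change cutoffs for quadrant
#'   assignment.
#' @return a `StructureExpressionTable` data.frame (`gene_a`, `gene_b`,
#'   `hic_A`, `hic_B`, `mi_A`, `mi_B`, `delta_hic`, `delta_mi`, `quadrant`)
#'   with attributes `r_A`, `r_B`, `r_delta`.
#' @export
structure_expression_analysis <- function(hicA, hicB, miA, miB, gene_bin_map,
                                          pseudocount = 1,
                                          mi_pseudocount = 0.01,
                                          hic_cutoff = 1, mi_cutoff = 0.5) {
  cn_assert(pseudocount > 0 && mi_pseudocount > 0,
            "pseudocounts must be positive")
  bin_of <- stats::setNames(gene_bin_map$bin_id, gene_bin_map$gene_id)
  pairs <- unique(rbind(miA[, c("gene_a", "gene_b")],
                        miB[, c("gene_a", "gene_b")]))
  pairs <- pairs[pairs$gene_a %in% names(bin_of) &
                   pairs$gene_b %in% names(bin_of), , drop = FALSE]
  bi <- bin_of[pairs$gene_a]; bj <- bin_of[pairs$gene_b]
  pairs <- pairs[bi != bj, , drop = FALSE]  # same-bin pairs have no Hi-C value
  bi <- bin_of[pairs$gene_a]; bj <- bin_of[pairs$gene_b]
  hic_lookup <- function(edges, i, j) {
    key <- paste(pmin(edges$bin_i, edges$bin_j),
                 pmax(edges$bin_i, edges$bin_j))
    v <- stats::setNames(edges$count, key)
    out <- unname(v[paste(pmin(i, j), pmax(i, j))])
    ifelse(is.na(out), 0, out)
  }
  mi_lookup <- function(mi, ga, gb) {
    key <- paste(pmin(mi$gene_a, mi$gene_b), pmax(mi$gene_a, mi$gene_b))
    v <- stats::setNames(mi$mi, key)
    out <- unname(v[paste(pmin(ga, gb), pmax(ga, gb))])
    ifelse(is.na(out), 0, out)
  }
  hA <- hic_lookup(hicA, bi, bj); hB <- hic_lookup(hicB, bi, bj)
  mA <- mi_lookup(miA, pairs$gene_a, pairs$gene_b)
  mB <- mi_lookup(miB, pairs$gene_a, pairs$gene_b)
  eligible <- (hA > 0 | hB > 0) & (mA > 0 | mB > 0)
  pairs <- pairs[eligible, , drop = FALSE]
  cn_assert(nrow(pairs) >= 3, "fewer than 3 eligible gene pairs",
            "chromanet_degenerate_error")
  hA <- hA[eligible]; hB <- hB[eligible]
  mA <- mA[eligible]; mB <- mB[eligible]
  dh <- log2((hB + pseudocount) / (hA + pseudocount))
  dm <- log2((mB + mi_pseudocount) / (mA + mi_pseudocount))
  quadrant <- rep("ns", nrow(pairs))
  sig <- abs(dh) > hic_cutoff & abs(dm) > mi_cutoff
  quadrant[sig & dh > 0 & dm > 0] <- "both-up"
  quadrant[sig & dh < 0 & dm < 0] <- "both-down"
  quadrant[sig & dh > 0 & dm < 0] <- "hic-up-mi-down"
  quadrant[sig & dh < 0 & dm > 0] <- "hic-down-mi-up"
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    hic_A = hA, hic_B = hB, mi_A = mA, mi_B = mB,
                    delta_hic = dh, delta_mi = dm, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  structure(out, r_A = safe_cor(hA, mA), r_B = safe_cor(hB, mB),
            r_delta = safe_cor(dh, dm),
            class = c("StructureExpressionTable", "data.frame"))
}
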