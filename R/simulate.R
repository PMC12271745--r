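#' Hi-C simulation parameters
#'
#' Defaults give the desk-scale study conditions: one 20 Mb synthetic
#' chromosome of 500 bins at 40 kb, one million contacts following a power-law
#' distance decay with exponent 1, 100 planted enriched contacts at 8-fold
#' enrichment, lognormal per-bin visibility biases (sd 0.2, clipped to
#' [0.5, 2]), and a tumor condition with 30% global contact loss, long-range
#' truncation at 5 Mb and 30% of peaks rewired.
#'
#' @param n_bins,resolution chromosome shape.
#' @param total_contacts total contact count of the normal map.
#' @param decay_exponent power-law decay exponent (alpha > 0); the per-pair
#'   contact probability is proportional to `(d / resolution)^-alpha`.
#' @param peak_count,peak_enrichment number of planted peaks and their
#'   enrichment factor (phi >= 1).
#' @param peak_max_distance bp; peaks are placed uniformly among pairs up to
#'   this separation (`NULL` for no bound). Default 5 Mb, the scale below
#'   which cohesin-mediated loops and enhancer-promoter contacts live.
#' @param bias_sd lognormal sd of per-bin biases (0 for no bias).
#' @param bias_clip range biases are clipped to.
#' @param tumor_loss_fraction global contact loss in the tumor map.
#' @param truncation_distance bp beyond which tumor contact probabilities fall
#'   to the background floor (the decay value at the maximum distance), or
#'   `NULL` for none.
#' @param rewire_fraction fraction of peaks moved to new random pairs in the
#'   tumor map.
#' @param peak_pairs optional data.frame (`bin_i`, `bin_j`) of pairs planted
#'   as peaks in addition to the `peak_count` random ones — used to couple
#'   chromatin peaks to co-expression module bins.
#' @param seed RNG seed.
#' @export
hic_sim_params <- function(n_bins = 500L, resolution = 40000L,
                           total_contacts = 1e6, decay_exponent = 1,
                           peak_count = 100L, peak_enrichment = 8,
                           peak_max_distance = 5e6,
                           bias_sd = 0.2, bias_clip = c(0.5, 2),
                           tumor_loss_fraction = 0.3,
                           truncation_distance = 5e6,
                           rewire_fraction = 0.3, peak_pairs = NULL,
                           seed = 1L) {
  p <- list(n_bins = as.integer(n_bins), resolution = as.integer(resolution),
            total_contacts = total_contacts, decay_exponent = decay_exponent,
            peak_count = as.integer(peak_count),
            peak_enrichment = peak_enrichment,
            peak_max_distance = peak_max_distance, bias_sd = bias_sd,
            bias_clip = bias_clip, tumor_loss_fraction = tumor_loss_fraction,
            truncation_distance = truncation_distance,
            rewire_fraction = rewire_fraction, peak_pairs = peak_pairs,
            seed = as.integer(seed))
  cn_assert(p$decay_exponent > 0, "decay_exponent must be > 0",
            "chromanet_parameter_error")
  cn_assert(p$peak_enrichment >= 1, "peak_enrichment must be >= 1",
            "chromanet_parameter_error")
  cn_assert(p$tumor_loss_fraction >= 0 && p$tumor_loss_fraction < 1,
            "tumor_loss_fraction in [0, 1)", "chromanet_parameter_error")
  cn_assert(p$rewire_fraction >= 0 && p$rewire_fraction <= 1,
            "rewire_fraction in [0, 1]", "chromanet_parameter_error")
  n_eligible <- if (is.null(p$peak_max_distance)) choose(p$n_bins, 2) else {
    dmax <- min(as.integer(p$peak_max_distance %/% p$resolution),
                p$n_bins - 1L)
    sum(p$n_bins - seq_len(dmax))
  }
  cn_assert(p$peak_count <= n_eligible,
            "peak_count exceeds available pairs in the peak distance range",
            "chromanet_parameter_error")
  class(p) <- "hic_sim_params"
  p
}

#' Simulate a paired normal/tumor Hi-C contact map with planted truth
#'
#' The normal map is a multinomial draw of `total_contacts` over all
#' off-diagonal bin pairs with probability proportional to
#' `d^-alpha * b_i * b_j`, times `peak_enrichment` on the planted peak pairs.
#' The tumor map uses the same biases with `total_contacts * (1 -
#' tumor_loss_fraction)` contacts; pairs beyond `truncation_distance` are
#' down-weighted to the background floor (the decay value at the chromosome's
#' maximum distance), and `rewire_fraction` of the peaks move to new random
#' pairs.
#'
#' @param params a [hic_sim_params()].
#' @return list with `normal` and `tumor` (`ContactMap`s) and `truth` (planted
#'   peak pairs per condition, the bias vector, the analytic per-distance
#'   decay weights, parameters).
#' @export
simulate_hic_pair <- function(params = hic_sim_params()) {
  set.seed(params$seed)
  nb <- params$n_bins
  res <- params$resolution
  pair_i <- rep(0:(nb - 2L), times = (nb - 1L):1L)
  pair_j <- unlist(lapply(1:(nb - 1L), function(a) a:(nb - 1L)),
                   use.names = FALSE)
  d_bins <- pair_j - pair_i
  bias <- if (params$bias_sd > 0) {
    pmin(pmax(stats::rlnorm(nb, 0, params$bias_sd), params$bias_clip[1]),
         params$bias_clip[2])
  } else rep(1, nb)
  base <- d_bins^(-params$decay_exponent) * bias[pair_i + 1L] * bias[pair_j + 1L]
  eligible <- if (is.null(params$peak_max_distance)) seq_along(base) else {
    which(d_bins * res <= params$peak_max_distance)
  }
  forced <- integer(0)
  if (!is.null(params$peak_pairs) && nrow(params$peak_pairs) > 0) {
    pp <- params$peak_pairs
    fi <- pmin(pp$bin_i, pp$bin_j); fj <- pmax(pp$bin_i, pp$bin_j)
    keep <- fi != fj
    forced <- unique(match(fi[keep] * nb + fj[keep], pair_i * nb + pair_j))
    cn_assert(!anyNA(forced), "peak_pairs outside the bin grid",
              "chromanet_parameter_error")
  }
  peaks <- sort(unique(c(forced,
                         sample(setdiff(eligible, forced),
                                params$peak_count))))
  w_normal <- base
  w_normal[peaks] <- w_normal[peaks] * params$peak_enrichment
  draw <- function(w, total) {
    counts <- as.vector(stats::rmultinom(1, total, w / sum(w)))
    nz <- counts > 0
    contact_map("chrS",
                data.frame(bin_i = pair_i[nz], bin_j = pair_j[nz],
                           count = counts[nz]),
                n_bins = nb, resolution = res)
  }
  normal <- draw(w_normal, params$total_contacts)
  # tumor: truncate long range to the decay floor, rewire part of the peaks
  floor_decay <- (nb - 1L)^(-params$decay_exponent)
  base_t <- base
  if (!is.null(params$truncation_distance)) {
    far <- d_bins * res > params$truncation_distance
    base_t[far] <- floor_decay * bias[pair_i[far] + 1L] * bias[pair_j[far] + 1L]
  }
  n_rewire <- round(params$rewire_fraction * length(peaks))
  rewired <- if (n_rewire > 0) sort(sample(peaks, n_rewire)) else integer(0)
  kept <- setdiff(peaks, rewired)
  new_peaks <- integer(0)
  if (n_rewire > 0) {
    pool <- setdiff(eligible, peaks)
    new_peaks <- sort(sample(pool, n_rewire))
  }
  peaks_t <- sort(c(kept, new_peaks))
  w_tumor <- base_t
  w_tumor[peaks_t] <- w_tumor[peaks_t] * params$peak_enrichment
  tumor <- draw(w_tumor, round(params$total_contacts *
                                 (1 - params$tumor_loss_fraction)))
  pk_df <- function(idx) data.frame(bin_i = pair_i[idx], bin_j = pair_j[idx])
  list(normal = normal, tumor = tumor,
       truth = list(peaks_normal = pk_df(peaks), peaks_tumor = pk_df(peaks_t),
                    bias = bias, params = params))
}

#' Expression simulation parameters
#'
#' Defaults give the desk-scale study conditions: 200 genes, 60 normal and 40
#' tumor samples, 8 modules of 10 spatially contiguous genes with
#' within-module correlation 0.8 on the latent scale, negative-binomial counts
#' with dispersion 0.05, sample library-size factors uniform in [0.75, 1.25],
#' and 30% of module genes reassigned to other modules in the tumor condition.
#'
#' @param n_genes,n_samples_normal,n_samples_tumor matrix shape.
#' @param n_modules,module_size planted co-expression modules.
#' @param within_module_correlation latent pairwise correlation rho in [0, 1).
#' @param noise_dispersion negative-binomial dispersion (1/size).
#' @param module_rewire_fraction fraction of module genes moved to a different
#'   module in the tumor condition.
#' @param library_size_range per-sample relative library-size factor range.
#' @param base_mean median expression level of the simulated genes.
#' @param seed RNG seed.
#' @export
expr_sim_params <- function(n_genes = 200L, n_samples_normal = 60L,
                            n_samples_tumor = 40L, n_modules = 8L,
                            module_size = 10L,
                            within_module_correlation = 0.8,
                            noise_dispersion = 0.05,
                            module_rewire_fraction = 0.3,
                            library_size_range = c(0.75, 1.25),
                            base_mean = 500, seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            n_samples_normal = as.integer(n_samples_normal),
            n_samples_tumor = as.integer(n_samples_tumor),
            n_modules = as.integer(n_modules),
            module_size = as.integer(module_size),
            within_module_correlation = within_module_correlation,
            noise_dispersion = noise_dispersion,
            module_rewire_fraction = module_rewire_fraction,
            library_size_range = library_size_range, base_mean = base_mean,
            seed = as.integer(seed))
  cn_assert(p$within_module_correlation >= 0 &&
              p$within_module_correlation < 1,
            "within_module_correlation in [0, 1)", "chromanet_parameter_error")
  cn_assert(p$n_modules * p$module_size <= p$n_genes,
            "modules exceed gene count", "chromanet_parameter_error")
  class(p) <- "expr_sim_params"
  p
}

# internal: counts for one condition given a module assignment
expr_condition_counts <- function(assign, params, n_samples, base, prefix) {
  rho <- params$within_module_correlation
  n_genes <- params$n_genes
  in_module <- !is.na(assign)
  factors <- matrix(stats::rnorm(params$n_modules * n_samples),
                    params$n_modules, n_samples)
  z <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  z[in_module, ] <- sqrt(rho) * factors[assign[in_module], , drop = FALSE] +
    sqrt(1 - rho) * z[in_module, , drop = FALSE]
  lib <- stats::runif(n_samples, params$library_size_range[1],
                      params$library_size_range[2])
  mu <- base * exp(z - 0.5) * rep(lib, each = n_genes)
  counts <- matrix(
    stats::rnbinom(n_genes * n_samples, mu = mu,
                   size = 1 / params$noise_dispersion),
    n_genes, n_samples)
  rownames(counts) <- names(assign)
  colnames(counts) <- paste0(prefix, seq_len(n_samples))
  counts
}

#' Simulate paired normal/tumor expression matrices with planted modules
#'
#' Latent-factor model: genes of module `m` share a per-sample factor with
#' loading `sqrt(rho)`, so latent pairwise within-module correlation is `rho`;
#' counts come from a negative-binomial observation layer with per-sample
#' library-size factors. The tumor condition reassigns
#' `module_rewire_fraction` of the module genes to other modules.
#'
#' @param params an [expr_sim_params()].
#' @param placement optional gene -> bin map (named integer vector); when
#'   given, module genes are chosen as spatially contiguous blocks of bins.
#' @return list with `normal` and `tumor` raw count matrices (genes x
#'   samples) and `truth` (module assignment per condition, changed genes,
#'   placement, params).
#' @export
simulate_expression_pair <- function(params = expr_sim_params(),
                                     placement = NULL) {
  set.seed(params$seed)
  n_genes <- params$n_genes
  gene_ids <- if (!is.null(placement)) {
    cn_assert(length(placement) >= n_genes, "placement must cover all genes")
    names(placement)[order(placement)][seq_len(n_genes)]
  } else sprintf("gene%03d", seq_len(n_genes))
  n_mod_genes <- params$n_modules * params$module_size
  assign_n <- rep(NA_integer_, n_genes)
  # contiguous blocks in placement (bin) order, so modules are spatially local
  assign_n[seq_len(n_mod_genes)] <- rep(seq_len(params$n_modules),
                                        each = params$module_size)
  names(assign_n) <- gene_ids
  assign_t <- assign_n
  movers <- which(!is.na(assign_n))
  movers <- sample(movers, round(params$module_rewire_fraction *
                                   length(movers)))
  if (length(movers) > 0 && params$n_modules > 1) {
    assign_t[movers] <- vapply(assign_n[movers], function(m) {
      sample(setdiff(seq_len(params$n_modules), m), 1)
    }, integer(1))
  }
  base <- stats::rlnorm(n_genes, log(params$base_mean), 0.4)
  normal <- expr_condition_counts(assign_n, params, params$n_samples_normal,
                                  base, "N")
  tumor <- expr_condition_counts(assign_t, params, params$n_samples_tumor,
                                 base, "T")
  list(normal = normal, tumor = tumor,
       truth = list(module_normal = assign_n, module_tumor = assign_t,
                    changed_genes = gene_ids[movers],
                    placement = placement, params = params))
}

#' Simulate a synthetic chromosome annotation
#'
#' One chromosome tiled at the given resolution, with TSSs placed so that each
#' occupied bin holds exactly one TSS, a fraction of genes typed as ncRNA, and
#' a fraction of bins blacklisted.
#'
#' @param n_bins,resolution chromosome shape.
#' @param gene_density fraction of bins holding one TSS (must be <= 1).
#' @param ncrna_fraction fraction of genes typed ncRNA.
#' @param blacklist_fraction fraction of bins covered by blacklist intervals.
#' @param seed RNG seed.
#' @return list with `bins` (`BinTable`), `genes` (gene records), `blacklist`
#'   (`RegionSet`) and `truth` (gene -> bin placement, blacklisted bins).
#' @export
simulate_genome_annotation <- function(n_bins = 500L, resolution = 40000L,
                                       gene_density = 0.4,
                                       ncrna_fraction = 0.2,
                                       blacklist_fraction = 0.02, seed = 1L) {
  cn_assert(gene_density >= 0 && gene_density <= 1,
            "gene_density too high to honour one TSS per bin",
            "chromanet_parameter_error")
  cn_assert(ncrna_fraction >= 0 && ncrna_fraction <= 1 &&
              blacklist_fraction >= 0 && blacklist_fraction <= 1,
            "fractions must lie in [0, 1]", "chromanet_parameter_error")
  set.seed(seed)
  bins <- bin_table(c(chrS = n_bins * resolution), resolution)
  n_genes <- round(gene_density * n_bins)
  gene_bins <- sort(sample.int(n_bins, n_genes)) - 1L
  tss <- gene_bins * resolution +
    sample.int(resolution - 1L, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  n_nc <- round(ncrna_fraction * n_genes)
  biotype <- rep("coding", n_genes)
  if (n_nc > 0) biotype[sample.int(n_genes, n_nc)] <- "ncRNA"
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    symbol = sprintf("SYM%03d", seq_len(n_genes)),
    chrom = "chrS", strand = strand, tss = tss, biotype = biotype,
    stringsAsFactors = FALSE)
  n_bl <- round(blacklist_fraction * n_bins)
  bl_bins <- if (n_bl > 0) sort(sample(setdiff(seq_len(n_bins) - 1L,
                                               gene_bins), n_bl)) else integer(0)
  blacklist <- region_set(rep("chrS", length(bl_bins)),
                          bl_bins * resolution,
                          (bl_bins + 1) * resolution, "blacklist")
  placement <- stats::setNames(gene_bins, genes$gene_id)
  list(bins = bins, genes = genes, blacklist = blacklist,
       truth = list(placement = placement, blacklist_bins = bl_bins))
}

#' Simulate a paired multilayer network with planted community changes
#'
#' Builds two two-layer networks (HIC bins + MI genes, one gene per bin,
#' interlayer edges of weight 1) whose nodes belong to strong clique modules
#' with sparse weak inter-module edges. The second condition moves
#' `move_fraction` of the nodes in `move_layers` to other modules.
#'
#' @param n_nodes nodes per layer.
#' @param n_modules number of planted modules.
#' @param move_fraction fraction of movable nodes reassigned in condition B.
#' @param move_layers layers whose nodes may move (`"HIC"`, `"MI"` or both).
#' @param w_in,w_out within-/between-module edge weights.
#' @param p_out probability of a between-module edge.
#' @param seed RNG seed.
#' @return list with `netA`, `netB` (igraphs with `layer` attributes),
#'   `truth` (`membership_A`, `membership_B`, `moved`, `layers`).
#' @export
simulate_community_pair <- function(n_nodes = 60L, n_modules = 4L,
                                    move_fraction = 0.3,
                                    move_layers = c("HIC", "MI"),
                                    w_in = 1, w_out = 0.05, p_out = 0.02,
                                    seed = 1L) {
  set.seed(seed)
  ids <- c(paste0("hic:", seq_len(n_nodes)), paste0("mi:", seq_len(n_nodes)))
  layers <- stats::setNames(rep(c("HIC", "MI"), each = n_nodes), ids)
  base_mod <- rep(seq_len(n_modules), length.out = n_nodes)[
    order(stats::runif(n_nodes))]
  membership_a <- stats::setNames(c(base_mod, base_mod), ids)
  movable <- ids[layers[ids] %in% move_layers]
  moved <- sample(movable, round(move_fraction * length(movable)))
  membership_b <- membership_a
  membership_b[moved] <- vapply(membership_a[moved], function(m) {
    sample(setdiff(seq_len(n_modules), m), 1)
  }, integer(1))
  build <- function(membership) {
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    g <- igraph::set_vertex_attr(g, "layer", value = unname(layers[ids]))
    edges <- character(0); ew <- numeric(0); el <- character(0)
    for (L in c("hic", "mi")) {
      members <- ids[startsWith(ids, paste0(L, ":"))]
      for (m in seq_len(n_modules)) {
        nodes <- members[membership[members] == m]
        if (length(nodes) >= 2) {
          cmb <- utils::combn(nodes, 2)
          edges <- c(edges, as.vector(cmb))
          ew <- c(ew, rep(w_in, ncol(cmb)))
          el <- c(el, rep(L, ncol(cmb)))
        }
      }
      cross <- utils::combn(members, 2)
      diff_mod <- membership[cross[1, ]] != membership[cross[2, ]]
      pick <- diff_mod & stats::runif(ncol(cross)) < p_out
      if (any(pick)) {
        edges <- c(edges, as.vector(cross[, pick, drop = FALSE]))
        ew <- c(ew, rep(w_out, sum(pick)))
        el <- c(el, rep(L, sum(pick)))
      }
    }
    inter <- rbind(paste0("mi:", seq_len(n_nodes)),
                   paste0("hic:", seq_len(n_nodes)))
    edges <- c(edges, as.vector(inter))
    ew <- c(ew, rep(1, n_nodes))
    el <- c(el, rep("interlayer", n_nodes))
    igraph::add_edges(g, edges, weight = ew, layer = el)
  }
  netA <- build(membership_a)
  netB <- build(membership_b)
  list(netA = netA, netB = netB,
       truth = list(membership_A = membership_a,
                    membership_B = membership_b, moved = moved,
                    layers = layers))
}

#' Simulate coupled structure-expression changes with quadrant truth
#'
#' Generates paired condition edge tables and MI networks for gene pairs with
#' planted change directions: each changed pair is assigned a quadrant
#' (`both-up`, `both-down`, `hic-up-mi-down`, `hic-down-mi-up`) — a
#' `concordant_fraction` of the changed pairs get concordant labels — and an
#' `ns_fraction` of pairs stay unchanged. When `coupled = FALSE`, Hi-C and MI
#' change directions are drawn independently per pair, decoupling the layers.
#'
#' @param n_pairs number of gene pairs.
#' @param concordant_fraction fraction of changed pairs with concordant
#'   Hi-C/MI direction (ignored when `coupled = FALSE`).
#' @param ns_fraction fraction of pairs without planted change.
#' @param coupled draw Hi-C and MI directions jointly (quadrant plan) or
#'   independently.
#' @param base_count baseline Hi-C contact count between a pair's bins.
#' @param fold Hi-C fold change of a planted "up"/"down".
#' @param mi_high,mi_low MI of a co-expressed vs censored pair.
#' @param noise_sd lognormal noise on counts and MI.
#' @param seed RNG seed.
#' @return list with `hicA`, `hicB` (edge tables), `miA`, `miB`
#'   (`MINetwork`s), `gene_bin_map` and `truth` (quadrant per pair).
#' @export
simulate_coupled_pair <- function(n_pairs = 200L, concordant_fraction = 0.6,
                                  ns_fraction = 0.2, coupled = TRUE,
                                  base_count = 30, fold = 8, mi_high = 0.7,
                                  mi_low = 0, noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  gene_a <- sprintf("gA%04d", seq_len(n_pairs))
  gene_b <- sprintf("gB%04d", seq_len(n_pairs))
  bin_a <- 2L * (seq_len(n_pairs) - 1L)
  bin_b <- bin_a + 1L
  n_ns <- round(ns_fraction * n_pairs)
  is_ns <- seq_len(n_pairs) %in% sample.int(n_pairs, n_ns)
  n_ch <- sum(!is_ns)
  if (coupled) {
    n_conc <- round(concordant_fraction * n_ch)
    lab <- c(rep(c("both-up", "both-down"), length.out = n_conc),
             rep(c("hic-up-mi-down", "hic-down-mi-up"),
                 length.out = n_ch - n_conc))
    lab <- sample(lab)
    hic_dir <- ifelse(lab %in% c("both-up", "hic-up-mi-down"), 1, -1)
    mi_dir <- ifelse(lab %in% c("both-up", "hic-down-mi-up"), 1, -1)
  } else {
    hic_dir <- sample(c(1, -1), n_ch, replace = TRUE)
    mi_dir <- sample(c(1, -1), n_ch, replace = TRUE)
    lab <- ifelse(hic_dir > 0,
                  ifelse(mi_dir > 0, "both-up", "hic-up-mi-down"),
                  ifelse(mi_dir > 0, "hic-down-mi-up", "both-down"))
  }
  quadrant <- rep("ns", n_pairs)
  quadrant[!is_ns] <- lab
  noisy <- function(x) x * stats::rlnorm(length(x), 0, noise_sd)
  hA <- rep(base_count, n_pairs); hB <- rep(base_count, n_pairs)
  hB[!is_ns][hic_dir > 0] <- base_count * fold
  hA[!is_ns][hic_dir < 0] <- base_count * fold
  mA <- rep(mi_high, n_pairs); mB <- rep(mi_high, n_pairs)
  mB[!is_ns][mi_dir < 0] <- mi_low
  mA[!is_ns][mi_dir > 0] <- mi_low
  hA <- pmax(round(noisy(hA)), 1); hB <- pmax(round(noisy(hB)), 1)
  mA <- ifelse(mA > 0, noisy(mA), 0); mB <- ifelse(mB > 0, noisy(mB), 0)
  mk_edges <- function(h) {
    data.frame(chrom = "chrS", bin_i = bin_a, bin_j = bin_b, count = h,
               distance_bp = 40000, omega = NA_real_, pvalue = NA_real_,
               qvalue = 1e-6, zscore = NA_real_, edge_type = NA_character_,
               stringsAsFactors = FALSE)
  }
  mk_mi <- function(m) {
    keep <- m > 0
    structure(
      data.frame(gene_a = gene_a[keep], gene_b = gene_b[keep], mi = m[keep],
                 support = 100L, pvalue = 0, stringsAsFactors = FALSE),
      lambda = NA_real_, B = 100L, mi_threshold = NA_real_,
      n_candidates = n_pairs, class = c("MINetwork", "data.frame"))
  }
  gene_bin_map <- data.frame(gene_id = c(gene_a, gene_b),
                             bin_id = c(bin_a, bin_b),
                             stringsAsFactors = FALSE)
  list(hicA = mk_edges(hA), hicB = mk_edges(hB),
       miA = mk_mi(mA), miB = mk_mi(mB), gene_bin_map = gene_bin_map,
       truth = list(quadrant = stats::setNames(quadrant,
                                               paste(gene_a, gene_b))))
}
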