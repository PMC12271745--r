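#' Run the full synthetic-mode analysis pipeline
#'
#' Executes the stages in order — simulate, balance, significance, networks,
#' comparison, co-expression, multilayer, structure-expression — on a
#' simulated normal/tumor pair, writing per-stage artifacts and a run manifest
#' (seeds, parameters, stage status) to `out_dir`. Deterministic given the
#' configuration seeds: re-running with the same seed produces byte-identical
#' edge tables, community tables and summaries.
#'
#' @param config a [chromanet_config()].
#' @param out_dir output directory (created if missing); `NULL` writes nothing.
#' @param hic_params,expr_params generator parameters; seeds default to the
#'   config's `rng_seed`.
#' @param genome a [simulate_genome_annotation()] result, or `NULL` to
#'   simulate one matching `hic_params`.
#' @param couple_peaks_to_modules also plant Hi-C peaks at the bin pairs of
#'   within-module gene pairs, so chromatin contacts and co-expression are
#'   spatially aligned (the study's premise) and the structure-expression
#'   stage has eligible pairs.
#' @return a `PipelineResult` list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config = chromanet_config(), out_dir = NULL,
                         hic_params = NULL, expr_params = NULL,
                         genome = NULL, couple_peaks_to_modules = TRUE) {
  validate_config(config)
  if (is.null(hic_params)) hic_params <- hic_sim_params(seed = config$rng_seed)
  if (is.null(expr_params)) {
    expr_params <- expr_sim_params(seed = config$rng_seed + 1L)
  }
  manifest <- list(config = unclass(config),
                   hic_params = unclass(hic_params),
                   expr_params = unclass(expr_params), stages = list())
  result <- list()
  stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      if (!is.null(out_dir)) write_manifest(manifest, out_dir)
      cn_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "chromanet_stage_error")
    })
    manifest$stages[[name]] <<- list(status = "complete")
    out
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  sim <- stage("simulate", function() {
    if (is.null(genome)) {
      genome <- simulate_genome_annotation(
        n_bins = hic_params$n_bins, resolution = hic_params$resolution,
        seed = config$rng_seed)
    }
    placement <- genome$truth$placement
    expr <- simulate_expression_pair(expr_params, placement = placement)
    if (couple_peaks_to_modules && is.null(hic_params$peak_pairs)) {
      mod <- expr$truth$module_normal
      mod <- mod[!is.na(mod)]
      pairs <- do.call(rbind, lapply(split(names(mod), mod), function(gs) {
        b <- sort(unique(unname(placement[gs])))
        if (length(b) < 2) return(NULL)
        cmb <- utils::combn(b, 2)
        data.frame(bin_i = cmb[1, ], bin_j = cmb[2, ])
      }))
      hic_params$peak_pairs <- pairs
    }
    hic <- simulate_hic_pair(hic_params)
    list(genome = genome, hic = hic, expr = expr)
  })

  balanced <- stage("balance", function() {
    list(normal = ice_balance(sim$hic$normal),
         tumor = ice_balance(sim$hic$tumor))
  })

  sig <- stage("significance", function() {
    lapply(stats::setNames(c("normal", "tumor"), c("normal", "tumor")),
           function(cond) {
             call_significant_interactions(
               sim$hic[[cond]], blacklist = sim$genome$blacklist,
               bias = balanced[[cond]]$bias,
               bias_bounds = config$bias_bounds,
               metabin_size = config$metabin_size,
               fdr_level = config$fdr_level)
           })
  })

  nets <- stage("networks", function() {
    lapply(sig, function(s) {
      e <- s$edges[s$edges$qvalue < config$q_threshold, , drop = FALSE]
      cn_assert(nrow(e) >= 2, "fewer than 2 network edges",
                "chromanet_degenerate_error")
      e <- compute_edge_zscores(e)
      net <- build_chromosome_network(e, sim$genome$bins, sim$genome$genes,
                                      q_threshold = config$q_threshold,
                                      keep_isolated = config$keep_isolated)
      list(edges = e, net = net)
    })
  })

  comparison <- stage("comparison", function() {
    di <- node_dissimilarity_profile(nets$normal$net, nets$tumor$net)
    knee <- tryCatch(kneedle_threshold(di$DI), error = function(e) NULL)
    list(
      jaccard_nodes = jaccard_similarity(nets$normal$net, nets$tumor$net,
                                         "nodes"),
      jaccard_edges = jaccard_similarity(nets$normal$net, nets$tumor$net,
                                         "edges"),
      jaccard_edge_type = jaccard_similarity(nets$normal$net, nets$tumor$net,
                                             "edge_type"),
      edge_logfc = interaction_count_logfc(nets$normal$net, nets$tumor$net),
      dissimilarity = di, kneedle = knee,
      metrics_normal = node_metrics(nets$normal$net),
      metrics_tumor = node_metrics(nets$tumor$net),
      decay_normal = decay_curve(balanced$normal$map),
      decay_tumor = decay_curve(balanced$tumor$map),
      census_normal = network_census(nets$normal$net),
      census_tumor = network_census(nets$tumor$net))
  })

  coexpr <- stage("coexpression", function() {
    counts <- cbind(sim$expr$normal, sim$expr$tumor)
    condition <- rep(c("normal", "tumor"),
                     c(ncol(sim$expr$normal), ncol(sim$expr$tumor)))
    expr <- preprocess_counts(counts, condition)
    thr <- estimate_mi_threshold(expr$norm, pvalue = config$mi_pvalue,
                                 seed = config$rng_seed)
    nets_mi <- lapply(stats::setNames(c("normal", "tumor"),
                                      c("normal", "tumor")),
                      function(cond) {
                        bootstrap_consensus_network(
                          expr$norm[, condition == cond, drop = FALSE],
                          B = config$n_bootstrap, mi_threshold = thr,
                          alpha = config$mi_consensus_alpha,
                          seed = config$rng_seed)
                      })
    list(expr = expr, threshold = thr, normal = nets_mi$normal,
         tumor = nets_mi$tumor)
  })

  multilayer <- stage("multilayer", function() {
    genes <- sim$genome$genes[sim$genome$genes$gene_id %in%
                                rownames(coexpr$expr$norm), , drop = FALSE]
    gb <- map_genes_to_bins(genes, sim$genome$bins)
    mlA <- assemble_multilayer(nets$normal$net, coexpr$normal, gb)
    mlB <- assemble_multilayer(nets$tumor$net, coexpr$tumor, gb)
    cA <- detect_communities(mlA, seed = config$louvain_seed)
    cB <- detect_communities(mlB, seed = config$louvain_seed)
    layers <- c(stats::setNames(igraph::V(mlA)$layer, igraph::V(mlA)$name),
                stats::setNames(igraph::V(mlB)$layer, igraph::V(mlB)$name))
    change <- membership_change_stats(cA, cB, layers = layers)
    list(gene_bin_map = gb, netA = mlA, netB = mlB, commA = cA, commB = cB,
         change = change)
  })

  strexp <- stage("structure_expression", function() {
    tryCatch(
      structure_expression_analysis(nets$normal$edges, nets$tumor$edges,
                                    coexpr$normal, coexpr$tumor,
                                    multilayer$gene_bin_map),
      chromanet_degenerate_error = function(e) NULL)
  })

  result <- list(sim = sim, balanced = balanced, significance = sig,
                 networks = nets, comparison = comparison,
                 coexpression = coexpr, multilayer = multilayer,
                 structure_expression = strexp, manifest = manifest)
  class(result) <- "PipelineResult"

  if (!is.null(out_dir)) {
    write_edge_table(nets$normal$edges, file.path(out_dir, "edges_normal.tsv"))
    write_edge_table(nets$tumor$edges, file.path(out_dir, "edges_tumor.tsv"))
    comm_tab <- data.frame(
      node = names(multilayer$commA$membership),
      community_normal = as.integer(multilayer$commA$membership),
      community_tumor = as.integer(
        multilayer$commB$membership[names(multilayer$commA$membership)]),
      stringsAsFactors = FALSE)
    utils::write.table(comm_tab, file.path(out_dir, "communities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary_json <- list(
      n_edges_normal = nrow(nets$normal$edges),
      n_edges_tumor = nrow(nets$tumor$edges),
      jaccard_nodes = comparison$jaccard_nodes,
      jaccard_edges = comparison$jaccard_edges,
      edge_logfc = comparison$edge_logfc,
      kneedle_threshold = if (!is.null(comparison$kneedle))
        comparison$kneedle$threshold else NA,
      mi_threshold = as.numeric(coexpr$threshold),
      n_mi_edges_normal = nrow(coexpr$normal),
      n_mi_edges_tumor = nrow(coexpr$tumor),
      community_change = multilayer$change)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(result$manifest, out_dir)
  }
  result
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}

#' @export
print.PipelineResult <- function(x, ...) {
  st <- vapply(x$manifest$stages, `[[`, "", "status")
  cat("PipelineResult:\n")
  for (nm in names(st)) cat(sprintf("  %-22s %s\n", nm, st[nm]))
  invisible(x)
}
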