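#' Pipeline configuration
#'
#' Bundles the tunable parameters of the pipeline with validation. Defaults
#' follow the study conditions: 40 kb bins, q < 0.001 network cut after an FDR
#' 0.05 family, bias bounds [0.5, 2], 200-pair metabins, MI significance at
#' p = 1e-8, 100 bootstrap networks.
#'
#' @param resolution bin width in bp.
#' @param q_threshold q-value cut for network edges (strict `<`).
#' @param fdr_level BH FDR level for the significance family.
#' @param bias_bounds length-2 numeric, admissible per-bin bias range.
#' @param metabin_size distance-ordered pairs per metabin for the decay fit.
#' @param mi_pvalue tail probability defining the MI significance threshold.
#' @param n_bootstrap number of bootstrap MI networks.
#' @param mi_consensus_alpha family-wise level of the Poisson consensus test
#'   (Bonferroni-corrected over candidate pairs).
#' @param louvain_seed,rng_seed seeds for community detection and everything
#'   else.
#' @param keep_isolated keep non-filtered bins as isolated network nodes.
#' @param paths named list of input/output paths (free-form; used by
#'   [run_pipeline()]).
#' @return a validated `chromanet_config` list.
#' @export
chromanet_config <- function(resolution = 40000L,
                             q_threshold = 0.001,
                             fdr_level = 0.05,
                             bias_bounds = c(0.5, 2),
                             metabin_size = 200L,
                             mi_pvalue = 1e-8,
                             n_bootstrap = 100L,
                             mi_consensus_alpha = 0.05,
                             louvain_seed = 42L,
                             rng_seed = 1L,
                             keep_isolated = FALSE,
                             paths = list()) {
  cfg <- list(resolution = as.integer(resolution), q_threshold = q_threshold,
              fdr_level = fdr_level, bias_bounds = as.numeric(bias_bounds),
              metabin_size = as.integer(metabin_size), mi_pvalue = mi_pvalue,
              n_bootstrap = as.integer(n_bootstrap),
              mi_consensus_alpha = mi_consensus_alpha,
              louvain_seed = as.integer(louvain_seed),
              rng_seed = as.integer(rng_seed),
              keep_isolated = isTRUE(keep_isolated), paths = paths)
  validate_config(cfg)
  class(cfg) <- "chromanet_config"
  cfg
}

validate_config <- function(cfg) {
  cn_assert(cfg$resolution >= 1, "resolution must be >= 1",
            "chromanet_config_error")
  cn_assert(cfg$q_threshold > 0 && cfg$q_threshold <= cfg$fdr_level &&
              cfg$fdr_level <= 1,
            "need 0 < q_threshold <= fdr_level <= 1", "chromanet_config_error")
  cn_assert(length(cfg$bias_bounds) == 2 &&
              cfg$bias_bounds[1] < cfg$bias_bounds[2],
            "bias_bounds must be (low, high) with low < high",
            "chromanet_config_error")
  cn_assert(cfg$metabin_size >= 2, "metabin_size must be >= 2",
            "chromanet_config_error")
  cn_assert(cfg$mi_pvalue > 0 && cfg$mi_pvalue < 1, "mi_pvalue in (0,1)",
            "chromanet_config_error")
  cn_assert(cfg$n_bootstrap >= 1, "n_bootstrap >= 1", "chromanet_config_error")
  invisible(cfg)
}

#' Read / write a YAML pipeline configuration
#' @param path YAML file with any subset of the [chromanet_config()] fields.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(chromanet_config, vals)
}

#' @rdname read_config
#' @param cfg a `chromanet_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
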