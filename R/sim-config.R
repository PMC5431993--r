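#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. Defaults define the reference study conditions used throughout the
#' test-suite: 200 samples, 1000 genes of which 5 planted modules of 40 genes
#' carry latent-factor structure with loadings drawn uniformly from
#' (0.5, 0.95), a BMI-like trait driven by the first module's factor plus an
#' age covariate, a planted standardized group difference of 1 in replicate
#' datasets, and miRNAs negatively coupled to targets with gamma = 0.5.
#'
#' @param n_samples Number of samples per simulated dataset.
#' @param n_genes Total number of genes (module genes plus background noise).
#' @param module_sizes Integer vector of planted module sizes; their sum must
#'   not exceed `n_genes`.
#' @param loading_range Length-2 numeric in (0, 1), low < high; per-gene factor
#'   loadings are drawn uniformly from this interval.
#' @param trait_effect Coefficient of the target module eigen-factor in the
#'   BMI-like trait model.
#' @param age_effect Coefficient of standardized age in the trait model.
#' @param trait_noise_sd Residual standard deviation of the trait model.
#' @param planted_smd Standardized mean shift applied (with negative sign) to
#'   planted module genes in the "obese" group of replicate datasets.
#' @param n_datasets Number of replicate datasets in the study collection.
#' @param mirna_gamma Coupling strength in (0, 1) between a targeting miRNA
#'   and its target gene (correlation is -gamma by construction).
#' @param dag_edges Data frame (parent, child, weight) describing a linear
#'   structural equation model planted inside the first module, or NULL.
#' @param seed Integer master seed; every component derives its own sub-stream
#'   deterministically from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 200L,
                       n_genes = 1000L,
                       module_sizes = rep(40L, 5L),
                       loading_range = c(0.5, 0.95),
                       trait_effect = 0.6,
                       age_effect = 0.3,
                       trait_noise_sd = 0.74,
                       planted_smd = 1.0,
                       n_datasets = 5L,
                       mirna_gamma = 0.5,
                       dag_edges = NULL,
                       seed = 1L) {
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (length(loading_range) != 2 || loading_range[1] <= 0 ||
      loading_range[2] >= 1 || loading_range[1] >= loading_range[2])
    stop("loading_range must satisfy 0 < low < high < 1")
  if (mirna_gamma < 0 || mirna_gamma > 1) stop("mirna_gamma must be in [0, 1]")
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  structure(list(
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    loading_range = as.numeric(loading_range),
    trait_effect = trait_effect,
    age_effect = age_effect,
    trait_noise_sd = trait_noise_sd,
    planted_smd = planted_smd,
    n_datasets = as.integer(n_datasets),
    mirna_gamma = mirna_gamma,
    dag_edges = dag_edges,
    seed = as.integer(seed)
  ), class = "sim_config")
}
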