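#' Default planted causal structure for the first module
#'
#' A layered DAG over 33 genes: one root regulator feeds eight intermediate
#' genes, each intermediate also receiving its own independent co-parent
#' (so every root-to-intermediate edge sits in a collider and the
#' equivalence class orients it from observational data), and each
#' intermediate feeds two downstream genes. The root is the planted key
#' driver: its directed out-degree (8) and 3-layer downstream neighbourhood
#' (24) dominate every other node.
#'
#' @param genes Character vector of at least 33 gene ids.
#' @param weight Edge weight of every structural equation (default 0.8).
#' @return List with `edges` (parent, child, weight) and `root` (gene id).
#' @export
default_causal_dag <- function(genes, weight = 0.8) {
  stopifnot(length(genes) >= 33)
  root <- genes[1]
  cop <- genes[2:9]; mid <- genes[10:17]; low <- genes[18:33]
  edges <- rbind(
    data.frame(parent = root, child = mid, weight = weight),
    data.frame(parent = cop, child = mid, weight = weight),
    data.frame(parent = rep(mid, each = 2), child = low, weight = weight)
  )
  list(edges = edges, root = root)
}

#' Generate the full synthetic input bundle
#'
#' Assembles every fixture the pipeline consumes: modular expression with
#' planted truth labels, a trait table driven by the first module's factor,
#' miRNAs targeting first-module genes, GWAS summary statistics with gene
#' models and an LD table (planted-module genes carry the association
#' signal), a linear-SEM causal fixture inside the first module, and a
#' replicate study collection carrying the planted group difference.
#'
#' @param cfg A [sim_config()].
#' @param n_mirna_targets Number of first-module genes assigned a targeting
#'   miRNA.
#' @return List of class `synthetic_bundle` with elements `expression`,
#'   `truth`, `factors`, `loadings`, `traits`, `mirna`, `target_table`,
#'   `gwas`, `causal` (expression, dag, root), `studies`, and `config`.
#' @export
simulate_bundle <- function(cfg = sim_config(), n_mirna_targets = 20L) {
  sim <- simulate_modular_expression(cfg)
  traits <- simulate_traits(sim$factors["mod1", ], cfg)

  mod1_genes <- sim$truth$gene_id[sim$truth$module == "mod1"]
  targets <- mod1_genes[seq_len(min(n_mirna_targets, length(mod1_genes)))]
  mir <- simulate_mirna(sim$expression, targets, gamma = cfg$mirna_gamma,
                        seed = component_seed(cfg$seed, "mirna"))

  planted <- sim$truth$gene_id[sim$truth$module != "background"]
  models <- make_gene_models(sim$truth$gene_id,
                             seed = component_seed(cfg$seed, "gwas"))
  gwas <- simulate_gwas_inputs(models, planted,
                               seed = component_seed(cfg$seed, "gwas") + 1L)

  dag <- cfg$dag_edges
  if (is.null(dag)) {
    dd <- default_causal_dag(mod1_genes)
    dag <- dd$edges
    root <- dd$root
  } else {
    root <- setdiff(dag$parent, dag$child)[1]
  }
  causal <- simulate_causal_module(dag, n_samples = max(cfg$n_samples, 500L),
                                   seed = component_seed(cfg$seed, "causal"))
  causal$root <- root

  studies <- simulate_study_collection(cfg, loadings = sim$loadings)

  hub_truth <- vapply(split(sim$truth$gene_id[sim$truth$module != "background"],
                            sim$truth$module[sim$truth$module != "background"]),
                      function(g) g[which.max(sim$loadings[g])], character(1))

  structure(list(
    expression = sim$expression, truth = sim$truth, factors = sim$factors,
    loadings = sim$loadings, traits = traits,
    mirna = mir$mirna, target_table = mir$target_table,
    gwas = gwas, causal = causal, studies = studies,
    hub_truth = hub_truth, key_driver_truth = root,
    config = cfg
  ), class = "synthetic_bundle")
}

#' Write a synthetic bundle to TSV fixture files
#'
#' Writes every component in the pipeline's plain-text input formats plus a
#' `truth.json` manifest of planted structure.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f, rn = FALSE) {
    path <- file.path(dir, f)
    if (rn) x <- data.frame(id = rownames(x), x, check.names = FALSE)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    w(bundle$expression, "expression.tsv", rn = TRUE),
    w(bundle$traits, "traits.tsv"),
    w(bundle$mirna, "mirna.tsv", rn = TRUE),
    w(bundle$target_table, "targets.tsv"),
    w(bundle$gwas$snps, "gwas_snps.tsv"),
    w(bundle$gwas$ld, "gwas_ld.tsv"),
    w(bundle$gwas$gene_models, "gene_models.tsv"),
    w(bundle$causal$expression, "causal_expression.tsv", rn = TRUE)
  )
  for (i in seq_along(bundle$studies)) {
    st <- bundle$studies[[i]]
    files <- c(files,
      w(st$expression, sprintf("study_%s_expression.tsv", st$study_id), rn = TRUE),
      w(data.frame(sample_id = colnames(st$expression), group = st$group),
        sprintf("study_%s_groups.tsv", st$study_id)))
  }
  truth <- list(
    module = stats::setNames(as.list(bundle$truth$module), bundle$truth$gene_id),
    hub_genes = as.list(bundle$hub_truth),
    key_driver = bundle$key_driver_truth,
    planted_delta = -bundle$config$planted_smd,
    seed = bundle$config$seed
  )
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(files, tp))
}
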