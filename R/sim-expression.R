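#' Simulate expression with planted latent-factor modules
#'
#' Each planted module m has a per-sample latent factor e_m ~ N(0, 1); member
#' gene i is x_i = w_i * e_m + sqrt(1 - w_i^2) * noise with loading w_i drawn
#' uniformly from `cfg$loading_range`. Background genes are pure noise. Rows
#' are standardized to mean 0, variance 1, so pairwise correlations within a
#' module are approximately w_i * w_j.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional override of the component sub-seed (defaults to a
#'   stream derived from `cfg$seed`).
#' @param loadings Optional explicit loading vector (one value per module
#'   gene, in module order) overriding the uniform draw; used to regenerate a
#'   dataset with the identical loading structure (e.g. a preserved test set).
#' @return List with `expression` (genes x samples matrix), `truth` (data
#'   frame gene_id, module — "background" for noise genes), `factors`
#'   (modules x samples), `loadings` (named per-gene).
#' @export
simulate_modular_expression <- function(cfg, seed = NULL, loadings = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- component_seed(cfg$seed, "expression")
  set.seed(seed)
  n <- cfg$n_samples
  g <- cfg$n_genes
  sizes <- cfg$module_sizes
  n_mod_genes <- sum(sizes)

  gene_ids <- sprintf("gene_%04d", seq_len(g))
  sample_ids <- sprintf("S%03d", seq_len(n))
  module_of <- rep("background", g)
  module_of[seq_len(n_mod_genes)] <-
    rep(sprintf("mod%d", seq_along(sizes)), sizes)

  factors <- matrix(stats::rnorm(length(sizes) * n), nrow = length(sizes),
                    ncol = n,
                    dimnames = list(sprintf("mod%d", seq_along(sizes)), sample_ids))
  if (is.null(loadings)) {
    loadings <- stats::runif(n_mod_genes, cfg$loading_range[1], cfg$loading_range[2])
  } else {
    stopifnot(length(loadings) == n_mod_genes)
  }
  names(loadings) <- gene_ids[seq_len(n_mod_genes)]

  x <- matrix(stats::rnorm(g * n), nrow = g,
              dimnames = list(gene_ids, sample_ids))
  for (i in seq_len(n_mod_genes)) {
    w <- loadings[i]
    x[i, ] <- w * factors[module_of[i], ] + sqrt(1 - w^2) * x[i, ]
  }
  x <- standardize_rows(x)
  list(expression = x,
       truth = data.frame(gene_id = gene_ids, module = module_of,
                          stringsAsFactors = FALSE),
       factors = factors,
       loadings = loadings)
}

#' Simulate a sample trait table driven by one module's factor
#'
#' Age is uniform on (30, 70). The BMI-like quantitative trait is
#' y = b1 * e_target + b2 * age_std + noise; the binary obesity label marks
#' the top 30% of y (70th-percentile threshold). Two extra quantitative
#' traits are generated as a positive and a negative correlate of the target
#' factor, mimicking metabolic phenotypes such as HOMA-IR and the Matsuda
#' index.
#'
#' @param e_target Numeric latent-factor vector, one value per sample.
#' @param cfg A [sim_config()] supplying `trait_effect`, `age_effect`,
#'   `trait_noise_sd` and the seed.
#' @param seed Optional sub-seed override.
#' @return Data frame: sample_id, obesity (0/1), bmi, age, homa_ir, matsuda.
#' @export
simulate_traits <- function(e_target, cfg, seed = NULL) {
  stopifnot(length(e_target) == cfg$n_samples)
  if (is.null(seed)) seed <- component_seed(cfg$seed, "traits")
  set.seed(seed)
  n <- cfg$n_samples
  age <- stats::runif(n, 30, 70)
  age_std <- as.numeric(scale(age))
  y <- cfg$trait_effect * e_target + cfg$age_effect * age_std +
    stats::rnorm(n, sd = cfg$trait_noise_sd)
  obesity <- as.integer(y > stats::quantile(y, 0.70))
  homa_ir <- 0.5 * e_target + stats::rnorm(n, sd = sqrt(1 - 0.25))
  matsuda <- -0.5 * e_target + stats::rnorm(n, sd = sqrt(1 - 0.25))
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             obesity = obesity, bmi = y, age = age,
             homa_ir = homa_ir, matsuda = matsuda,
             stringsAsFactors = FALSE)
}

#' Simulate expression from a linear structural equation model
#'
#' Genes are generated in topological order of the supplied DAG:
#' x_child = sum(w * x_parent) + N(0, 1) noise. Roots are standard normal.
#'
#' @param dag_edges Data frame with columns parent, child, weight. May have
#'   zero rows (independent genes).
#' @param genes Character vector of gene ids (must cover all edge endpoints);
#'   defaults to the ids occurring in `dag_edges`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return List with `expression` (genes x samples, standardized) and `dag`
#'   (the input edge table).
#' @export
simulate_causal_module <- function(dag_edges, genes = NULL, n_samples = 500L,
                                   seed = 1L) {
  if (is.null(dag_edges) || nrow(dag_edges) == 0) {
    dag_edges <- data.frame(parent = character(), child = character(),
                            weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(genes))
    genes <- unique(c(dag_edges$parent, dag_edges$child))
  stopifnot(all(c(dag_edges$parent, dag_edges$child) %in% genes))
  # topological order; igraph errors on cyclic input
  if (nrow(dag_edges) > 0) {
    gr <- igraph::graph_from_data_frame(dag_edges[, c("parent", "child")],
                                        vertices = genes)
    if (!igraph::is_dag(gr)) stop("dag_edges contain a cycle")
    ord <- names(igraph::topo_sort(gr))
  } else {
    ord <- genes
  }
  set.seed(seed)
  n <- as.integer(n_samples)
  x <- matrix(NA_real_, nrow = length(genes), ncol = n,
              dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  for (gid in ord) {
    val <- stats::rnorm(n)
    par_rows <- dag_edges[dag_edges$child == gid, , drop = FALSE]
    if (nrow(par_rows) > 0) {
      for (r in seq_len(nrow(par_rows)))
        val <- val + par_rows$weight[r] * x[par_rows$parent[r], ]
    }
    x[gid, ] <- val
  }
  list(expression = standardize_rows(x), dag = dag_edges)
}

#' Simulate miRNA expression negatively coupled to target genes
#'
#' A targeting miRNA j is miR_j = -gamma * x_target(j) + sqrt(1 - gamma^2) *
#' noise, so its population correlation with the target is exactly -gamma
#' (rows standardized). Non-targeting miRNAs are pure noise.
#'
#' @param expression Genes x samples matrix (standardized rows).
#' @param targets Character vector of target gene ids, one per targeting
#'   miRNA; must be a subset of rownames(expression).
#' @param gamma Coupling strength in [0, 1].
#' @param n_noise Number of additional pure-noise miRNAs.
#' @param seed Integer seed.
#' @return List with `mirna` (miRNAs x samples matrix) and `target_table`
#'   (data frame mirna_id, gene_id for the targeting miRNAs).
#' @export
simulate_mirna <- function(expression, targets, gamma = 0.5, n_noise = 20L,
                           seed = 1L) {
  bad <- setdiff(targets, rownames(expression))
  if (length(bad) > 0)
    stop("unknown target gene id(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  n <- ncol(expression)
  n_t <- length(targets)
  ids <- c(sprintf("miR_t%03d", seq_len(n_t)),
           if (n_noise > 0) sprintf("miR_n%03d", seq_len(n_noise)))
  m <- matrix(stats::rnorm((n_t + n_noise) * n), nrow = n_t + n_noise,
              dimnames = list(ids, colnames(expression)))
  for (j in seq_len(n_t)) {
    m[j, ] <- -gamma * expression[targets[j], ] + sqrt(1 - gamma^2) * m[j, ]
  }
  if (nrow(m) > 0) m <- standardize_rows(m)
  list(mirna = m,
       target_table = data.frame(mirna_id = ids[seq_len(n_t)],
                                 gene_id = targets,
                                 stringsAsFactors = FALSE))
}
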