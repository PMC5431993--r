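#' Simulate a collection of replicate case/control expression datasets
#'
#' Each study regenerates expression with the discovery loading structure
#' (same per-gene loadings, fresh factors and noise), splits samples into an
#' equal-size non-obese (0) / obese (1) contrast, and shifts every planted
#' module gene by `-delta` within-group standard deviations in the obese
#' group. Optionally appends one dataset whose gene identities are randomly
#' permuted, destroying the module structure from the reference's point of
#' view (a non-preserved test set).
#'
#' @param cfg A [sim_config()]; `cfg$n_datasets` studies are generated with
#'   `cfg$n_samples` samples each.
#' @param loadings Per-gene loading vector from the discovery simulation
#'   ([simulate_modular_expression()]); freshly drawn if NULL.
#' @param delta Planted standardized shift (defaults to `cfg$planted_smd`).
#' @param include_scrambled Append the scrambled dataset as the last study?
#' @return List of class `study_collection`: each element has `expression`,
#'   `group` (0/1 per sample), `study_id`, `scrambled` flag; attribute
#'   `truth_delta` gives the planted per-gene shift (negative for module
#'   genes, 0 for background).
#' @export
simulate_study_collection <- function(cfg, loadings = NULL,
                                      delta = cfg$planted_smd,
                                      include_scrambled = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_datasets >= 1)
  base_seed <- component_seed(cfg$seed, "studies")
  if (is.null(loadings)) {
    # all studies must share one loading structure
    set.seed(base_seed)
    loadings <- stats::runif(sum(cfg$module_sizes),
                             cfg$loading_range[1], cfg$loading_range[2])
  }
  n <- cfg$n_samples
  n_obese <- n %/% 2
  group <- c(rep(0L, n - n_obese), rep(1L, n_obese))

  make_study <- function(k, scrambled = FALSE) {
    sim <- simulate_modular_expression(
      cfg, seed = base_seed + 1000L * k,
      loadings = loadings
    )
    x <- sim$expression
    if (scrambled) {
      set.seed(component_seed(cfg$seed, "scramble") + k)
      rownames(x) <- rownames(x)[sample(nrow(x))]
      x <- x[order(rownames(x)), , drop = FALSE]
    }
    is_module <- sim$truth$module != "background"
    shifted <- if (scrambled) rep(FALSE, nrow(x)) else is_module
    if (delta != 0 && any(shifted)) {
      # rows are standardized; the pooled within-group SD is ~1 before the
      # shift, so -delta is the planted standardized mean difference
      x[shifted, group == 1L] <- x[shifted, group == 1L] - delta
    }
    list(expression = x, group = group,
         study_id = if (scrambled) "scrambled" else sprintf("study%d", k),
         scrambled = scrambled)
  }

  studies <- lapply(seq_len(cfg$n_datasets), make_study)
  if (include_scrambled)
    studies <- c(studies, list(make_study(cfg$n_datasets + 1L, scrambled = TRUE)))

  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  truth_delta <- c(rep(-delta, sum(cfg$module_sizes)),
                   rep(0, cfg$n_genes - sum(cfg$module_sizes)))
  names(truth_delta) <- gene_ids
  structure(studies, class = "study_collection", truth_delta = truth_delta)
}

#' Generate random non-overlapping gene models
#'
#' Places genes on chromosomes 1..22 with random transcript spans and
#' strands, leaving at least 10 kb between neighbours so promoter windows
#' never collide.
#'
#' @param gene_ids Character vector of gene ids.
#' @param seed Integer seed.
#' @return Data frame: gene_id, chr, start, end, strand.
#' @export
make_gene_models <- function(gene_ids, seed = 1L) {
  set.seed(seed)
  g <- length(gene_ids)
  chr <- sprintf("chr%d", sample(1:22, g, replace = TRUE))
  models <- do.call(rbind, lapply(split(seq_len(g), chr), function(idx) {
    starts <- cumsum(sample(12000:50000, length(idx), replace = TRUE)) + 100000L
    len <- sample(1000:8000, length(idx), replace = TRUE)
    data.frame(gene_id = gene_ids[idx], chr = chr[idx[1]],
               start = starts, end = starts + len,
               strand = sample(c("+", "-"), length(idx), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(models) <- NULL
  models[order(match(models$gene_id, gene_ids)), , drop = FALSE]
}

#' Simulate GWAS summary statistics and an LD table over gene models
#'
#' Each gene receives 1-20 SNPs uniformly placed in its transcript plus
#' 1-kb upstream window (strand-aware). Genes in `planted_genes` get a
#' minimum SNP p-value drawn uniform(0, 0.05); background genes uniform(0, 1)
#' — so planted genes pass the nominal gene-wide threshold by construction.
#' SNPs within a gene are grouped into proxy clusters of 1-4 with pairwise
#' r-squared 0.9 recorded in the LD table.
#'
#' @param gene_models Data frame from [make_gene_models()].
#' @param planted_genes Character vector of gene ids meant to be selected.
#' @param seed Integer seed.
#' @return List with `snps` (snp_id, chr, pos, p), `ld` (snp_a, snp_b, r2)
#'   and the input `gene_models`.
#' @export
simulate_gwas_inputs <- function(gene_models, planted_genes, seed = 1L) {
  bad <- setdiff(planted_genes, gene_models$gene_id)
  if (length(bad) > 0)
    stop("planted gene(s) not in gene_models: ", paste(bad, collapse = ", "))
  set.seed(seed)
  snp_rows <- list()
  ld_rows <- list()
  snp_counter <- 0L
  for (i in seq_len(nrow(gene_models))) {
    gm <- gene_models[i, ]
    k <- sample(1:20, 1)
    window <- if (gm$strand == "+") c(gm$start - 1000L, gm$end)
              else c(gm$start, gm$end + 1000L)
    pos <- sort(sample(window[1]:window[2], k, replace = FALSE))
    pmin_target <- if (gm$gene_id %in% planted_genes)
      stats::runif(1, 0, 0.05) else stats::runif(1, 0, 1)
    p <- stats::runif(k, pmin_target, 1)
    p[sample(k, 1)] <- pmin_target
    ids <- sprintf("rs%06d", snp_counter + seq_len(k))
    snp_counter <- snp_counter + k
    snp_rows[[i]] <- data.frame(snp_id = ids, chr = gm$chr, pos = pos, p = p,
                                stringsAsFactors = FALSE)
    # proxy clusters of 1-4 consecutive SNPs, r2 = 0.9 within
    cl <- cumsum(stats::runif(k) < 0.4)
    for (c_id in unique(cl)) {
      members <- ids[cl == c_id]
      if (length(members) > 1) {
        pairs <- utils::combn(members, 2)
        ld_rows[[length(ld_rows) + 1]] <-
          data.frame(snp_a = pairs[1, ], snp_b = pairs[2, ], r2 = 0.9,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(snps = do.call(rbind, snp_rows),
       ld = if (length(ld_rows) > 0) do.call(rbind, ld_rows)
            else data.frame(snp_a = character(), snp_b = character(),
                            r2 = numeric(), stringsAsFactors = FALSE),
       gene_models = gene_models)
}
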