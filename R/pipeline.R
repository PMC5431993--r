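#' Build a pipeline configuration
#'
#' @param input_dir Directory holding the fixture TSVs (layout of
#'   [write_bundle()]).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, in dependency order a
#'   subset of c("gwas", "qc", "network", "causal", "mirna", "preserve",
#'   "meta").
#' @param beta Soft-thresholding power (NULL = choose by scale-free fit).
#' @param alpha_gwas Gene-wide significance threshold.
#' @param alpha_ci PC conditional-independence level.
#' @param h Key-driver neighbourhood depth.
#' @param mm_cut,gs_cut Hub criteria.
#' @param fdr_cut FDR cutoffs (miRNA and meta stages).
#' @param min_module_size Minimum module size.
#' @param n_perm Preservation permutations.
#' @param B Meta permutation count (0 disables).
#' @param seed Integer seed for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            stages = c("gwas", "qc", "network", "causal",
                                       "mirna", "preserve", "meta"),
                            beta = 6, alpha_gwas = 0.05, alpha_ci = 0.01,
                            h = 3L, mm_cut = 0.8, gs_cut = 0.2,
                            fdr_cut = 0.05, min_module_size = 30L,
                            n_perm = 100L, B = 0L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every referenced path and parameter range, accumulating problems
#' rather than failing on the first.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  known <- c("gwas", "qc", "network", "causal", "mirna", "preserve", "meta")
  if (!all(config$stages %in% known))
    add(paste("unknown stage(s):",
              paste(setdiff(config$stages, known), collapse = ", ")))
  if (!dir.exists(config$input_dir))
    add(paste("input_dir does not exist:", config$input_dir))
  else {
    need <- c(gwas = "gwas_snps.tsv", qc = "expression.tsv",
              network = "traits.tsv", causal = "causal_expression.tsv",
              mirna = "mirna.tsv", meta = "study_study1_expression.tsv")
    for (st in intersect(config$stages, names(need)))
      if (!file.exists(file.path(config$input_dir, need[[st]])))
        add(paste0("missing input for stage ", st, ": ", need[[st]]))
  }
  if (!is.null(config$beta) && config$beta < 1) add("beta must be >= 1")
  if (config$alpha_gwas <= 0 || config$alpha_gwas >= 1)
    add("alpha_gwas must be in (0, 1)")
  if (config$alpha_ci <= 0 || config$alpha_ci >= 1)
    add("alpha_ci must be in (0, 1)")
  if (config$h < 1) add("h must be >= 1")
  if (config$n_perm < 50) add("n_perm must be >= 50")
  errs
}

config_hash <- function(config) {
  # small FNV-1a over the deparsed config; enough to tag outputs
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]), collapse = "")
  h <- 21661364
  for (b in utf8ToInt(s)) h <- (bitwXor(h, b) * 65599) %% 2147483647
  sprintf("%08x", as.integer(h))
}

read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Run the full three-stage pipeline
#'
#' Executes the requested stages in dependency order (gwas, qc, network,
#' causal, mirna, preserve, meta) against the fixture files in
#' `config$input_dir`, writing one TSV per result plus a MANIFEST of
#' completed stages. Every output carries the configuration hash as a
#' comment header. On a stage error the MANIFEST of completed stages is
#' written before the error propagates.
#'
#' @param config A [pipeline_config()] (validated first; any problem
#'   aborts).
#' @return Invisibly, the list of per-stage results.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid configuration:\n", paste("-", errs, collapse = "\n"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  ind <- config$input_dir
  done <- character()
  results <- list()
  logf <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(stage, msg)
    cat(sprintf("%s stage=%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, msg), file = logf, append = TRUE)
  emit <- function(d, f) {
    path <- file.path(config$out_dir, f)
    writeLines(sprintf("# config_hash=%s", hash), path)
    suppressWarnings(utils::write.table(d, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE,
                                        col.names = TRUE))
  }
  manifest <- function() {
    writeLines(c(sprintf("config_hash\t%s", hash),
                 sprintf("stage\t%s", done)),
               file.path(config$out_dir, "MANIFEST"))
  }
  on.exit(manifest())

  run <- function(stage) stage %in% config$stages

  candidates <- NULL
  if (run("gwas")) {
    log_line("gwas", "start")
    snps <- utils::read.table(file.path(ind, "gwas_snps.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    ld <- utils::read.table(file.path(ind, "gwas_ld.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    models <- utils::read.table(file.path(ind, "gene_models.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    gp <- gene_wide_pvalue(assign_snps_to_genes(snps, models), snps, ld)
    candidates <- select_candidate_genes(gp, alpha = config$alpha_gwas)
    emit(gp, "gene_pvalues.tsv")
    emit(data.frame(gene_id = candidates), "candidate_genes.tsv")
    results$gwas <- gp
    done <- c(done, "gwas"); log_line("gwas", "done")
  }

  expr <- read_matrix_tsv(file.path(ind, "expression.tsv"))
  if (run("qc")) {
    log_line("qc", "start")
    det_path <- file.path(ind, "detection.tsv")
    if (file.exists(det_path))
      expr <- detection_filter(expr, read_matrix_tsv(det_path))
    expr <- knn_impute(expr)
    outliers <- detect_outlier_samples(expr)
    if (nrow(outliers) > 0)
      expr <- expr[, !colnames(expr) %in% outliers$sample_id, drop = FALSE]
    emit(outliers, "outlier_samples.tsv")
    emit(data.frame(id = rownames(expr), expr, check.names = FALSE),
         "qc_expression.tsv")
    results$qc <- outliers
    done <- c(done, "qc"); log_line("qc", "done")
  }

  traits <- utils::read.table(file.path(ind, "traits.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  traits <- traits[match(colnames(expr), traits$sample_id), ]

  labels <- NULL; trait_module <- NULL
  if (run("network")) {
    log_line("network", "start")
    net_expr <- if (!is.null(candidates))
      expr[rownames(expr) %in% candidates, , drop = FALSE] else expr
    beta <- config$beta
    if (is.null(beta)) beta <- pick_soft_threshold(net_expr)$beta
    adj <- adjacency(net_expr, beta = beta)
    diss <- 1 - tom(adj)
    labels <- cluster_modules(diss, min_module_size = config$min_module_size,
                              expr = net_expr)
    mes <- module_eigengenes(net_expr, labels)
    mta <- do.call(rbind, lapply(colnames(mes), function(m) {
      res <- module_trait_association(mes[, m], traits$obesity, traits$age)
      cbind(module = m, trait = "obesity", res)
    }))
    gs <- vapply(rownames(net_expr), function(g)
      gene_significance(net_expr[g, ], traits$obesity)$gs, numeric(1))
    mm <- module_membership(net_expr, mes)
    hubs <- identify_hub_genes(labels, gs = gs, kme = mm$kme,
                               mm_cut = config$mm_cut, gs_cut = config$gs_cut)
    trait_module <- mta$module[which.min(mta$p)]
    emit(data.frame(gene_id = names(labels), module = labels), "modules.tsv")
    emit(data.frame(sample_id = rownames(mes), mes, check.names = FALSE),
         "eigengenes.tsv")
    emit(mta, "module_trait.tsv")
    emit(data.frame(gene_id = names(gs), module = labels[names(gs)], gs = gs,
                    kme_own = vapply(names(gs), function(g)
                      if (labels[g] == "grey") NA_real_
                      else mm$kme[g, labels[g]], numeric(1))),
         "gs_mm.tsv")
    emit(data.frame(module = rep(names(hubs), lengths(hubs)),
                    gene_id = unlist(hubs)), "hubs.tsv")
    results$network <- list(labels = labels, mes = mes, mta = mta,
                            trait_module = trait_module, beta = beta)
    done <- c(done, "network"); log_line("network", "done")
  }

  if (run("causal")) {
    log_line("causal", "start")
    cexpr <- read_matrix_tsv(file.path(ind, "causal_expression.tsv"))
    graph <- pc_algorithm(cexpr, alpha = config$alpha_ci)
    kda <- key_driver_analysis(graph, rownames(cexpr), h = config$h)
    emit(causal_edges(graph), "causal_edges.tsv")
    emit(data.frame(gene_id = names(kda$mu), hln_size = kda$mu,
                    out_degree = kda$out_degree,
                    causal_regulator = names(kda$mu) %in% kda$causal_regulators,
                    key_driver = names(kda$mu) %in% kda$key_drivers),
         "key_drivers.tsv")
    results$causal <- kda
    done <- c(done, "causal"); log_line("causal", "done")
  }

  if (run("mirna")) {
    log_line("mirna", "start")
    mirna <- read_matrix_tsv(file.path(ind, "mirna.tsv"))
    targets <- utils::read.table(file.path(ind, "targets.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    mrna <- if (!is.null(labels))
      expr[rownames(expr) %in% names(labels)[labels != "grey"], , drop = FALSE]
      else expr
    pairs <- correlate_pairs(mrna, mirna[, colnames(mrna), drop = FALSE])
    inter <- filter_and_select(pairs, targets, fdr_cut = config$fdr_cut)
    emit(inter, "interactions.tsv")
    results$mirna <- inter
    done <- c(done, "mirna"); log_line("mirna", "done")
  }

  if (run("preserve")) {
    log_line("preserve", "start")
    test <- read_matrix_tsv(file.path(ind, "study_study1_expression.tsv"))
    mod_genes <- if (!is.null(labels) && !is.null(trait_module))
      names(labels)[labels == trait_module]
      else rownames(expr)[seq_len(min(100, nrow(expr)))]
    pres <- zsummary(expr, test, mod_genes,
                     beta = if (is.null(config$beta)) 6 else config$beta,
                     n_perm = config$n_perm, seed = config$seed)
    emit(data.frame(module = if (is.null(trait_module)) "manual"
                    else trait_module,
                    Zdensity = pres$Zdensity,
                    Zconnectivity = pres$Zconnectivity,
                    Zsummary = pres$Zsummary,
                    n_permutations = pres$n_permutations),
         "preservation.tsv")
    results$preserve <- pres
    done <- c(done, "preserve"); log_line("preserve", "done")
  }

  if (run("meta")) {
    log_line("meta", "start")
    sfiles <- list.files(ind, pattern = "^study_.*_expression\\.tsv$")
    studies <- lapply(sfiles, function(f) {
      gid <- sub("_expression\\.tsv$", "_groups.tsv", f)
      grp <- utils::read.table(file.path(ind, gid), header = TRUE, sep = "\t")
      list(expression = read_matrix_tsv(file.path(ind, f)), group = grp$group)
    })
    meta <- meta_analyze(studies, B = config$B, seed = config$seed)
    emit(meta, "meta_results.tsv")
    results$meta <- meta
    done <- c(done, "meta"); log_line("meta", "done")
  }

  invisible(results)
}
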