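#' Assign SNPs to genes within the transcript plus 1-kb promoter window
#'
#' A SNP belongs to a gene when its position falls in the transcript span
#' extended 1 kb upstream of the transcription start (strand-aware:
#' [start - upstream_bp, end] on the plus strand, [start, end + upstream_bp]
#' on the minus strand). A SNP may belong to several overlapping genes.
#'
#' @param snps Data frame: snp_id, chr, pos (1-based), p in (0, 1].
#' @param genes Data frame: gene_id, chr, start, end (1-based inclusive),
#'   strand ("+"/"-").
#' @param upstream_bp Promoter extension in base pairs.
#' @return Named list mapping gene_id to the character vector of member
#'   snp_ids (genes with no SNPs are omitted).
#' @export
assign_snps_to_genes <- function(snps, genes, upstream_bp = 1000L) {
  check_snp_table(snps)
  check_gene_table(genes)
  out <- list()
  snps_by_chr <- split(snps, snps$chr)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- snps_by_chr[[g$chr]]
    if (is.null(s)) next
    win <- if (g$strand == "+") c(g$start - upstream_bp, g$end)
           else c(g$start, g$end + upstream_bp)
    hit <- s$snp_id[s$pos >= win[1] & s$pos <= win[2]]
    if (length(hit) > 0) out[[g$gene_id]] <- hit
  }
  out
}

check_snp_table <- function(snps) {
  need <- c("snp_id", "chr", "pos", "p")
  if (!all(need %in% names(snps)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(snps$pos) | snps$pos < 1 |
               !is.finite(snps$p) | snps$p <= 0 | snps$p > 1)
  if (length(bad) > 0)
    stop("malformed SNP record(s) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

check_gene_table <- function(genes) {
  need <- c("gene_id", "chr", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  bad <- which(genes$start > genes$end | !genes$strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("malformed gene record(s) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Cluster SNPs into LD proxy groups
#'
#' Single-linkage connected components of the graph whose edges join SNP
#' pairs in high LD. Missing pairs are treated as r-squared 0; SNPs with no
#' qualifying partner are singleton clusters.
#'
#' @param snp_set Character vector of SNP ids.
#' @param ld_table Data frame: snp_a, snp_b, r2 (symmetric pairs need not be
#'   duplicated).
#' @param r2_threshold LD threshold, default 0.80.
#' @param direction ">=" (default: cluster pairs at or above the threshold)
#'   or "<=".
#' @return List of character vectors, one per cluster.
#' @export
cluster_snps_by_ld <- function(snp_set, ld_table, r2_threshold = 0.80,
                               direction = c(">=", "<=")) {
  direction <- match.arg(direction)
  if (length(snp_set) == 0) return(list())
  keep <- ld_table$snp_a %in% snp_set & ld_table$snp_b %in% snp_set
  edges <- ld_table[keep, , drop = FALSE]
  edges <- if (direction == ">=") edges[edges$r2 >= r2_threshold, , drop = FALSE]
           else edges[edges$r2 <= r2_threshold, , drop = FALSE]
  gr <- igraph::graph_from_data_frame(edges[, c("snp_a", "snp_b")],
                                      directed = FALSE, vertices = snp_set)
  comp <- igraph::components(gr)$membership
  unname(split(names(comp), comp))
}

#' Gene-wide p-values by the minimum-p rule over proxy clusters
#'
#' Each LD proxy cluster scores the minimum p-value of its members; the gene
#' scores the minimum over its clusters (equivalently, the minimum over all
#' member SNPs — the clustering affects the reported cluster count, not the
#' minimum).
#'
#' @param gene_snp_map Output of [assign_snps_to_genes()].
#' @param snps SNP table carrying the p-values.
#' @param ld_table LD table passed to [cluster_snps_by_ld()].
#' @param r2_threshold,direction Forwarded to [cluster_snps_by_ld()].
#' @return Data frame: gene_id, p_gene, n_snps, n_clusters; genes with no
#'   SNPs are absent.
#' @export
gene_wide_pvalue <- function(gene_snp_map, snps, ld_table,
                             r2_threshold = 0.80, direction = ">=") {
  p_of <- stats::setNames(snps$p, snps$snp_id)
  rows <- lapply(names(gene_snp_map), function(gid) {
    members <- gene_snp_map[[gid]]
    if (any(!members %in% names(p_of)))
      stop("SNP without p-value in gene ", gid)
    clusters <- cluster_snps_by_ld(members, ld_table, r2_threshold, direction)
    cluster_p <- vapply(clusters, function(cl) min(p_of[cl]), numeric(1))
    data.frame(gene_id = gid, p_gene = min(cluster_p),
               n_snps = length(members), n_clusters = length(clusters),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select nominally significant GWAS genes
#'
#' Inclusive threshold: genes with gene-wide p <= alpha.
#'
#' @param gene_pvalues Data frame from [gene_wide_pvalue()].
#' @param alpha Significance level, default 0.05.
#' @return Character vector of selected gene ids.
#' @export
select_candidate_genes <- function(gene_pvalues, alpha = 0.05) {
  if (nrow(gene_pvalues) == 0) return(character())
  gene_pvalues$gene_id[gene_pvalues$p_gene <= alpha]
}
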