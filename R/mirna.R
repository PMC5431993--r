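#' Correlate all miRNA-mRNA pairs
#'
#' Pearson correlation of every (miRNA, gene) combination across the shared
#' samples, with p-values from the t transform on n - 2 df. The default
#' sidedness tests for negative correlation (lower tail), matching the
#' biology of miRNA-mediated repression; two-sided testing is available.
#'
#' @param mrna_expr Genes x samples matrix.
#' @param mirna_expr miRNAs x samples matrix over the same samples, in the
#'   same order.
#' @param sidedness "one_sided_negative" (default) or "two_sided".
#' @return Data frame: mirna_id, gene_id, r, p_cor (one row per pair).
#' @export
correlate_pairs <- function(mrna_expr, mirna_expr,
                            sidedness = c("one_sided_negative", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (!identical(colnames(mrna_expr), colnames(mirna_expr)))
    stop("mRNA and miRNA matrices must share identically ordered samples")
  n <- ncol(mrna_expr)
  r <- stats::cor(t(mirna_expr), t(mrna_expr))   # miRNA x gene
  p <- cor_pvalue(r, n, alternative = if (sidedness == "one_sided_negative")
    "less" else "two.sided")
  data.frame(
    mirna_id = rep(rownames(r), times = ncol(r)),
    gene_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p_cor = as.vector(p),
    stringsAsFactors = FALSE
  )
}

#' Select database-supported negatively correlated interactions
#'
#' Restricts the correlated pairs to those predicted by the target database,
#' adjusts the correlation p-values by Benjamini-Hochberg across exactly
#' that restricted set, and marks as selected the pairs with negative
#' correlation and FDR below the cutoff.
#'
#' @param pairs Data frame from [correlate_pairs()].
#' @param target_table Data frame: mirna_id, gene_id (optionally
#'   p_database, carried through).
#' @param fdr_cut FDR threshold, default 0.05.
#' @return Data frame: mirna_id, gene_id, r, p_cor, fdr, selected (plus
#'   p_database when supplied).
#' @export
filter_and_select <- function(pairs, target_table, fdr_cut = 0.05) {
  key <- function(d) paste(d$mirna_id, d$gene_id, sep = "\r")
  keep <- key(pairs) %in% key(target_table)
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no correlated pair is supported by the target database")
    out$fdr <- numeric(0)
    out$selected <- logical(0)
    return(out)
  }
  if ("p_database" %in% names(target_table)) {
    m <- match(key(out), key(target_table))
    out$p_database <- target_table$p_database[m]
  }
  out$fdr <- stats::p.adjust(out$p_cor, method = "BH")
  out$selected <- out$r < 0 & out$fdr < fdr_cut
  rownames(out) <- NULL
  out
}
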