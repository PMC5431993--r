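# Standard module colour sequence, assigned by decreasing module size.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

#' Detect coexpression modules from the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on 1 - TOM followed by a two-pass
#' branch cut: (1) a static cut at 0.99 times the maximum merge height
#' (background genes pair at dissimilarity near the maximum, so branches
#' that complete below this line are candidate modules);
#' candidate branches of at least `min_module_size` genes whose mean
#' intra-branch dissimilarity is below `tightness` times the overall mean
#' dissimilarity become modules (the tightness check rejects apparent
#' branches in structureless data, where every dissimilarity sits near the
#' maximum); (2) when `expr` is supplied, unassigned genes are attached to
#' the module of maximal eigengene correlation (kME) when that kME exceeds
#' `kme_attach`. Remaining genes are labelled "grey". Module labels are
#' colour names assigned by decreasing module size (turquoise, blue, ...).
#'
#' @param dissTOM Symmetric dissimilarity matrix in [0, 1] (1 - TOM).
#' @param min_module_size Minimum branch size, default 30 (must be >= 3).
#' @param deep_split Accepted for interface compatibility; unused.
#' @param expr Optional genes x samples matrix enabling the kME attachment
#'   pass.
#' @param kme_attach kME threshold for attaching unassigned genes.
#' @param tightness Intra-branch vs overall mean-dissimilarity ratio a
#'   candidate must beat.
#' @return Named character vector: gene id -> module colour ("grey" =
#'   unassigned).
#' @export
cluster_modules <- function(dissTOM, min_module_size = 30L, deep_split = 2L,
                            expr = NULL, kme_attach = 0.3, tightness = 0.98) {
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  genes <- rownames(dissTOM)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(dissTOM)))
  hc <- stats::hclust(stats::as.dist(dissTOM), method = "average")
  # ties can leave heights unsorted by ~1e-16, which cutree rejects
  hc$height <- round(hc$height, 12)
  cut_h <- 0.99 * max(hc$height)
  branch <- stats::cutree(hc, h = cut_h)

  overall <- mean(dissTOM[upper.tri(dissTOM)])
  keep <- c()
  for (b in unique(branch)) {
    idx <- which(branch == b)
    if (length(idx) < min_module_size) next
    intra <- mean(dissTOM[idx, idx][upper.tri(diag(length(idx)))])
    if (intra < tightness * overall) keep <- c(keep, b)
  }
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  if (length(keep) == 0) return(labels)

  sizes <- vapply(keep, function(b) sum(branch == b), integer(1))
  keep <- keep[order(sizes, decreasing = TRUE)]
  for (i in seq_along(keep)) {
    col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i]
           else sprintf("module%d", i)
    labels[branch == keep[i]] <- col
  }

  if (!is.null(expr) && any(labels == "grey")) {
    mes <- module_eigengenes(expr, labels)
    kme <- abs(stats::cor(t(expr), mes))
    for (g in genes[labels == "grey"]) {
      best <- which.max(kme[g, ])
      if (kme[g, best] > kme_attach) labels[g] <- colnames(kme)[best]
    }
  }
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix, scaled to unit variance and
#' sign-aligned so that the average member gene correlates positively with
#' it.
#'
#' @param expr Genes x samples matrix.
#' @param labels Named module assignment from [cluster_modules()]; "grey"
#'   genes are ignored.
#' @return Samples x modules matrix of eigengene values.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  stopifnot(length(mods) > 0)
  n <- ncol(expr)
  mes <- matrix(NA_real_, nrow = n, ncol = length(mods),
                dimnames = list(colnames(expr), mods))
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 2) stop("module ", m, " has fewer than 2 genes")
    sub <- standardize_rows(expr[genes, , drop = FALSE])
    sv <- svd(t(sub), nu = 1, nv = 0)            # samples x genes
    me <- sv$u[, 1]
    me <- me / stats::sd(me)
    if (mean(stats::cor(t(sub), me)) < 0) me <- -me
    mes[, m] <- me
  }
  mes
}

#' Age-adjusted module-trait association
#'
#' Partial Pearson correlation of an eigengene and a trait controlling for
#' age (correlation of the two sets of residuals after regressing out age),
#' with a two-sided p-value from the t transform on n - 3 degrees of
#' freedom. Binary traits enter as 0/1.
#'
#' @param me Eigengene vector (length n samples).
#' @param trait Numeric or 0/1 trait vector.
#' @param age Covariate vector.
#' @return Data frame: r (partial correlation), p, r_squared.
#' @export
module_trait_association <- function(me, trait, age) {
  stopifnot(length(me) == length(trait), length(me) == length(age))
  if (stats::sd(trait) == 0) stop("trait has zero variance")
  res_me <- stats::resid(stats::lm(me ~ age))
  res_tr <- stats::resid(stats::lm(trait ~ age))
  r <- stats::cor(res_me, res_tr)
  n <- length(me)
  df <- n - 3
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  data.frame(r = r, p = 2 * stats::pt(-abs(tt), df), r_squared = r^2)
}

#' Gene significance for a trait
#'
#' GS = |Pearson correlation of a gene's expression with the (0/1) obesity
#' label| with its two-sided p-value.
#'
#' @param expr_row Numeric expression vector for one gene.
#' @param obesity 0/1 (or numeric) trait vector.
#' @return Data frame: gs, p.
#' @export
gene_significance <- function(expr_row, obesity) {
  if (stats::sd(expr_row) == 0 || stats::sd(obesity) == 0)
    stop("constant input")
  n <- length(expr_row)
  stopifnot(n >= 4, length(obesity) == n)
  r <- stats::cor(expr_row, obesity)
  data.frame(gs = abs(r), p = cor_pvalue(r, n))
}

#' Module membership (kME) of every gene for every module
#'
#' kME_q(i) = |cor(x_i, ME_q)|, reported for members and non-members alike,
#' with two-sided correlation p-values.
#'
#' @param expr Genes x samples matrix.
#' @param mes Samples x modules eigengene matrix.
#' @return List: `kme` and `p`, both genes x modules.
#' @export
module_membership <- function(expr, mes) {
  r <- stats::cor(t(expr), mes)
  list(kme = abs(r), p = cor_pvalue(r, ncol(expr)))
}

#' Identify module hub genes
#'
#' Two definitions: `criteria` returns, per module, the member genes with
#' own-module kME strictly above `mm_cut` and GS strictly above `gs_cut`;
#' `max_connectivity` returns the single member with the largest
#' intramodular connectivity (sum of adjacency to the other members), ties
#' broken by gene id order.
#'
#' @param labels Named module assignment.
#' @param gs Named GS vector (required for `criteria` mode).
#' @param kme Genes x modules kME matrix (required for `criteria` mode).
#' @param adj [adjacency()] object or matrix (required for
#'   `max_connectivity` mode).
#' @param mm_cut,gs_cut Strict thresholds for the criteria mode.
#' @param mode "criteria" or "max_connectivity".
#' @return Named list: module -> character vector of hub gene ids.
#' @export
identify_hub_genes <- function(labels, gs = NULL, kme = NULL, adj = NULL,
                               mm_cut = 0.8, gs_cut = 0.2,
                               mode = c("criteria", "max_connectivity")) {
  mode <- match.arg(mode)
  mods <- setdiff(unique(labels), "grey")
  out <- list()
  for (m in mods) {
    members <- sort(names(labels)[labels == m])
    if (mode == "criteria") {
      stopifnot(!is.null(gs), !is.null(kme))
      hit <- members[kme[members, m] > mm_cut & gs[members] > gs_cut]
      out[[m]] <- hit
    } else {
      stopifnot(!is.null(adj))
      a <- if (inherits(adj, "adjacency")) adj$a else adj
      kim <- rowSums(a[members, members, drop = FALSE])
      out[[m]] <- members[which.max(kim)]   # which.max takes first = id order
    }
  }
  out
}

#' Hypergeometric category enrichment of a module
#'
#' For each category: fold enrichment (k/n)/(K/N) and the upper-tail
#' hypergeometric probability of observing at least k module genes in the
#' category, Bonferroni-adjusted across the tested categories.
#'
#' @param module_genes Character vector (subset of `universe`).
#' @param category_map Named list: category -> character vector of genes.
#' @param universe Character vector of all genes considered.
#' @return Data frame: category, n_overlap, fold, p, p_bonferroni.
#' @export
enrichment_test <- function(module_genes, category_map, universe) {
  stopifnot(all(module_genes %in% universe))
  N <- length(universe)
  n <- length(module_genes)
  rows <- list()
  for (cat in names(category_map)) {
    cat_genes <- intersect(category_map[[cat]], universe)
    K <- length(cat_genes)
    if (K == 0) {
      warning("category ", cat, " absent from universe; skipped")
      next
    }
    k <- length(intersect(cat_genes, module_genes))
    fold <- (k / n) / (K / N)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[cat]] <- data.frame(category = cat, n_overlap = k, fold = fold,
                              p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(category = character(),
                                      n_overlap = integer(), fold = numeric(),
                                      p = numeric(), p_bonferroni = numeric()))
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}
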