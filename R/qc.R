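#' Remove probes not detected above background
#'
#' A gene is removed when its detection p-value is at or above `p_cut` in at
#' least `frac` of the samples (both comparisons inclusive) — i.e. it is not
#' significantly expressed above background in essentially all subjects.
#'
#' @param expr Genes x samples matrix.
#' @param detection_p Same-shape matrix of detection p-values in [0, 1].
#' @param p_cut Detection p-value cutoff, default 0.01.
#' @param frac Fraction of samples, default 0.90.
#' @return The filtered expression matrix (possibly with fewer rows).
#' @export
detection_filter <- function(expr, detection_p, p_cut = 0.01, frac = 0.90) {
  if (missing(detection_p) || is.null(detection_p))
    stop("no detection p-value matrix supplied; skip the detection filter stage")
  stopifnot(identical(dim(expr), dim(detection_p)))
  n_undetected <- rowSums(detection_p >= p_cut)
  expr[n_undetected < frac * ncol(expr), , drop = FALSE]
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Each missing cell is replaced by the mean, at that sample, of the `k`
#' genes nearest to the target gene (Euclidean distance over the samples
#' where both genes are observed, normalized by the overlap size). Genes
#' missing in half or more of the samples are dropped with a warning. When
#' no neighbour is observed at the sample, the gene's row mean is used.
#'
#' @param expr Genes x samples matrix possibly containing NA.
#' @param k Number of neighbours, default 10.
#' @return Complete matrix; observed cells are untouched.
#' @export
knn_impute <- function(expr, k = 10L) {
  if (k >= nrow(expr)) stop("k must be smaller than the number of genes")
  miss_frac <- rowMeans(is.na(expr))
  if (any(miss_frac >= 0.5)) {
    warning("dropping ", sum(miss_frac >= 0.5),
            " gene(s) with >= 50% missing values")
    expr <- expr[miss_frac < 0.5, , drop = FALSE]
  }
  if (!anyNA(expr)) return(expr)
  out <- expr
  incomplete <- which(rowSums(is.na(expr)) > 0)
  for (i in incomplete) {
    xi <- expr[i, ]
    obs_i <- !is.na(xi)
    # mean squared difference over shared observed samples
    d2 <- apply(expr, 1, function(xj) {
      shared <- obs_i & !is.na(xj)
      if (!any(shared)) return(Inf)
      mean((xi[shared] - xj[shared])^2)
    })
    d2[i] <- Inf
    nn <- order(d2)[seq_len(k)]
    for (s in which(is.na(xi))) {
      vals <- expr[nn, s]
      vals <- vals[!is.na(vals)]
      out[i, s] <- if (length(vals) > 0) mean(vals) else mean(xi, na.rm = TRUE)
    }
  }
  out
}

#' Flag outlier samples by first principal component and clustering height
#'
#' Samples are scored on the first principal component of the sample x gene
#' matrix; average-linkage hierarchical clustering of inter-sample Euclidean
#' distances supplies per-sample join heights. A sample is flagged when its
#' |PC1 z-score| exceeds `z_cut`, or when it joins the dendrogram as a
#' singleton at a height above mean + `z_cut` * sd of all merge heights.
#'
#' @param expr Genes x samples matrix (at least 10 samples).
#' @param z_cut Threshold in SD units, default 3.
#' @return Data frame: sample_id, pc1_z, flagged_pc1, flagged_dendro — one
#'   row per flagged sample (zero rows when no outlier).
#' @export
detect_outlier_samples <- function(expr, z_cut = 3.0) {
  if (ncol(expr) < 10) stop("at least 10 samples required")
  sx <- t(expr)
  pc1 <- stats::prcomp(sx, center = TRUE, scale. = FALSE)$x[, 1]
  z <- (pc1 - mean(pc1)) / stats::sd(pc1)
  flag_pc1 <- abs(z) > z_cut

  hc <- stats::hclust(stats::dist(sx), method = "average")
  h_cut <- mean(hc$height) + z_cut * stats::sd(hc$height)
  # height at which each singleton sample joins the tree
  join_h <- rep(NA_real_, ncol(expr))
  for (m in seq_len(nrow(hc$merge))) {
    for (side in 1:2) {
      v <- hc$merge[m, side]
      if (v < 0) join_h[-v] <- hc$height[m]
    }
  }
  flag_dendro <- join_h > h_cut

  flagged <- flag_pc1 | flag_dendro
  data.frame(sample_id = colnames(expr)[flagged],
             pc1_z = unname(z[flagged]),
             flagged_pc1 = flag_pc1[flagged],
             flagged_dendro = flag_dendro[flagged],
             row.names = NULL, stringsAsFactors = FALSE)
}
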