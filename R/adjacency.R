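#' Soft-threshold adjacency matrix
#'
#' a_ij = |Pearson cor(x_i, x_j)|^beta. Raising |cor| to a power beta > 1
#' pushes weak correlations toward 0 while preserving strong ones, which is
#' what gives the weighted network its approximately scale-free degree
#' distribution. The diagonal is set to 0 so connectivity sums exclude the
#' self term.
#'
#' @param expr Genes x samples matrix, at least 3 samples, no constant rows.
#' @param beta Soft-thresholding power, default 6.
#' @return List of class `adjacency`: `a` (genes x genes), `beta`.
#' @export
adjacency <- function(expr, beta = 6) {
  if (ncol(expr) < 3) stop("at least 3 samples required")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  structure(list(a = a, beta = beta), class = "adjacency")
}

#' Connectivity (weighted degree) of every gene
#'
#' k_i = sum over u != i of a_ui.
#'
#' @param adj An [adjacency()] object or plain symmetric matrix with zero
#'   diagonal.
#' @return Named numeric vector.
#' @export
connectivity <- function(adj) {
  a <- if (inherits(adj, "adjacency")) adj$a else adj
  rowSums(a)
}

#' Scale-free topology fitting index
#'
#' Bins the connectivities into `n_bins` equal-width bins, regresses
#' log10(frequency) on log10(mean connectivity) over non-empty bins, and
#' returns R-squared signed by the negated slope: positive when frequency
#' decays with connectivity (the scale-free direction), negative otherwise.
#'
#' @param k Numeric connectivity vector with at least `n_bins` distinct
#'   values.
#' @param n_bins Number of bins, default 10.
#' @return Signed R-squared.
#' @export
scale_free_fit_index <- function(k, n_bins = 10L) {
  if (length(unique(k)) < n_bins)
    stop("fewer than n_bins distinct connectivity values (degenerate network)")
  bins <- cut(k, breaks = n_bins)
  freq <- tabulate(bins, nbins = n_bins)
  mean_k <- tapply(k, bins, mean)
  keep <- freq > 0 & !is.na(mean_k) & mean_k > 0
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- suppressWarnings(summary(fit)$r.squared)   # perfect fits are fine here
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Choose the smallest soft threshold reaching scale-free fit
#'
#' Evaluates the signed scale-free fitting index of the network adjacency at
#' each candidate power and returns the smallest power whose index reaches
#' `r2_target`; if none does, the power of maximal index is returned with a
#' warning.
#'
#' @param expr Genes x samples matrix.
#' @param betas Ascending candidate powers, default 1..20.
#' @param r2_target Signed R-squared target, default 0.8.
#' @param n_bins Bins for [scale_free_fit_index()].
#' @return List: `beta` (selected), `fit` (data frame beta, r2).
#' @export
pick_soft_threshold <- function(expr, betas = 1:20, r2_target = 0.8,
                                n_bins = 10L) {
  stopifnot(!is.unsorted(betas))
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  r2 <- vapply(betas, function(b) {
    k <- rowSums(ac^b)
    tryCatch(scale_free_fit_index(k, n_bins), error = function(e) NA_real_)
  }, numeric(1))
  fit <- data.frame(beta = betas, r2 = r2)
  ok <- which(!is.na(r2) & r2 >= r2_target)
  if (length(ok) > 0) {
    beta <- betas[ok[1]]
  } else {
    warning("no candidate power reaches the scale-free target; ",
            "returning the power with maximal fit")
    beta <- betas[which.max(r2)]
  }
  list(beta = beta, fit = fit)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' k_i the connectivity. Two genes score high overlap when they are strongly
#' connected to each other and share the same neighbours. Diagonal is 1 by
#' convention; 1 - TOM is the clustering dissimilarity.
#'
#' @param adj An [adjacency()] object or plain adjacency matrix with zero
#'   diagonal.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom <- function(adj) {
  a <- if (inherits(adj, "adjacency")) adj$a else adj
  k <- rowSums(a)
  shared <- a %*% a                       # diag(a) = 0 so u != i, j
  denom <- outer(k, k, pmin) + 1 - a
  t_mat <- (shared + a) / denom
  diag(t_mat) <- 1
  t_mat
}
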