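#' Observed module preservation statistics
#'
#' Density statistics ask whether the module stays internally connected in
#' the test data: `meanCor` is the mean signed off-diagonal intra-module
#' correlation and `meanAdj` the mean intra-module soft-threshold adjacency,
#' both computed in the test dataset. Connectivity statistics ask whether
#' the wiring is similar across datasets: `cor_kIM` correlates the
#' intramodular connectivity vectors of reference and test, `cor_cor`
#' correlates the vectorized intra-module correlation matrices.
#'
#' @param ref_expr,test_expr Genes x samples matrices; the module genes
#'   present in both are used (their fraction is reported).
#' @param module_genes Character vector of module gene ids.
#' @param beta Soft threshold for `meanAdj`, default 6.
#' @return List: meanCor, meanAdj, cor_kIM, cor_cor, n_genes,
#'   fraction_shared.
#' @export
preservation_stats <- function(ref_expr, test_expr, module_genes, beta = 6) {
  shared <- intersect(intersect(module_genes, rownames(ref_expr)),
                      rownames(test_expr))
  if (length(shared) < 4) stop("fewer than 4 shared module genes")
  cr <- stats::cor(t(ref_expr[shared, , drop = FALSE]))
  ct <- stats::cor(t(test_expr[shared, , drop = FALSE]))
  ut <- upper.tri(cr)
  ar <- abs(cr)^beta; diag(ar) <- 0
  at <- abs(ct)^beta; diag(at) <- 0
  list(
    meanCor = mean(ct[ut]),
    meanAdj = mean(at[ut]),
    cor_kIM = stats::cor(rowSums(ar), rowSums(at)),
    cor_cor = stats::cor(cr[ut], ct[ut]),
    n_genes = length(shared),
    fraction_shared = length(shared) / length(module_genes)
  )
}

#' Permutation Zsummary module preservation
#'
#' The observed preservation statistics are compared with a permutation null
#' in which the module label is reassigned to random gene sets of equal size
#' drawn from all test-network genes (a draw identical to the observed set
#' is redrawn). Each statistic is standardized as
#' Z = (observed - mean_permuted) / sd_permuted; Zdensity is the median of
#' the two density Z's, Zconnectivity the median of the two connectivity
#' Z's, and Zsummary their mean. Rule-of-thumb thresholds: Zsummary < 2 no
#' evidence of preservation, 2-10 weak to moderate, >= 10 strong.
#'
#' @inheritParams preservation_stats
#' @param n_perm Number of permutations (>= 50), default 100.
#' @param seed Integer seed for the permutation draws.
#' @return List of class `preservation_result`: `observed`, `perm_mean`,
#'   `perm_sd`, `Z` (per statistic), `Zdensity`, `Zconnectivity`,
#'   `Zsummary`, `n_permutations`.
#' @export
zsummary <- function(ref_expr, test_expr, module_genes, beta = 6,
                     n_perm = 100L, seed = 1L) {
  if (n_perm < 50) stop("n_perm must be >= 50")
  stats_names <- c("meanCor", "meanAdj", "cor_kIM", "cor_cor")
  obs <- preservation_stats(ref_expr, test_expr, module_genes, beta)
  m <- obs$n_genes
  pool <- intersect(rownames(ref_expr), rownames(test_expr))
  obs_set <- sort(intersect(module_genes, pool))

  set.seed(seed)
  perm <- matrix(NA_real_, nrow = n_perm, ncol = 4,
                 dimnames = list(NULL, stats_names))
  for (b in seq_len(n_perm)) {
    repeat {
      draw <- sample(pool, m)
      if (!identical(sort(draw), obs_set)) break
    }
    ps <- preservation_stats(ref_expr, test_expr, draw, beta)
    perm[b, ] <- unlist(ps[stats_names])
  }
  mu <- colMeans(perm)
  sdv <- apply(perm, 2, stats::sd)
  z <- (unlist(obs[stats_names]) - mu) / sdv
  if (any(sdv == 0)) {
    warning("zero permutation sd; Z set to +Inf")
    z[sdv == 0] <- Inf
  }
  zden <- stats::median(z[c("meanCor", "meanAdj")])
  zcon <- stats::median(z[c("cor_kIM", "cor_cor")])
  structure(list(observed = obs, perm_mean = mu, perm_sd = sdv, Z = z,
                 Zdensity = zden, Zconnectivity = zcon,
                 Zsummary = mean(c(zden, zcon)),
                 n_permutations = n_perm),
            class = "preservation_result")
}
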