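# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# triple-loop TOM oracle (paper formula, no matrix algebra)
tom_brute <- function(a) {
  p <- nrow(a)
  k <- sapply(seq_len(p), function(i) sum(a[-i, i]))
  t_mat <- matrix(1, p, p, dimnames = dimnames(a))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(p)) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
    t_mat[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t_mat
}

# recursive partial-correlation oracle (independent of matrix inversion)
pcor_recursive <- function(corr, i, j, S) {
  if (length(S) == 0) return(corr[i, j])
  k <- S[1]; rest <- S[-1]
  rij <- pcor_recursive(corr, i, j, rest)
  rik <- pcor_recursive(corr, i, k, rest)
  rjk <- pcor_recursive(corr, j, k, rest)
  (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
}

# random correlation matrix (positive definite) over p variables
random_corr <- function(p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(4 * p * p), ncol = p)
  cor(x %*% matrix(rnorm(p * p), p, p))
}

# random sparse linear SEM over up to `p` nodes; returns data + true edges
random_sem <- function(p, n, seed, edge_prob = 0.4) {
  set.seed(seed)
  nodes <- sprintf("v%d", seq_len(p))
  edges <- data.frame(parent = character(), child = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < edge_prob) {
      edges <- rbind(edges, data.frame(
        parent = nodes[i], child = nodes[j],
        weight = sample(c(-1, 1), 1) * runif(1, 0.4, 0.9)))
    }
  }
  x <- matrix(rnorm(p * n), nrow = p, dimnames = list(nodes, NULL))
  for (j in seq_len(p)) {
    pr <- edges[edges$child == nodes[j], , drop = FALSE]
    for (r in seq_len(nrow(pr)))
      x[j, ] <- x[j, ] + pr$weight[r] * x[pr$parent[r], ]
  }
  colnames(x) <- sprintf("s%d", seq_len(n))
  list(expression = x, edges = edges, nodes = nodes)
}

# exhaustive-CI skeleton oracle: edge absent iff ANY subset of the other
# nodes yields a non-rejected CI test
brute_skeleton <- function(expr, alpha = 0.01) {
  nodes <- sort(rownames(expr))
  corr <- cor(t(expr))
  n <- ncol(expr)
  p <- length(nodes)
  amat <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(amat) <- FALSE
  for (i in nodes) for (j in nodes[nodes > i]) {
    others <- setdiff(nodes, c(i, j))
    for (sz in 0:length(others)) {
      if (n - sz - 3 <= 0) break
      sets <- if (sz == 0) list(character()) else
        combn(others, sz, simplify = FALSE)
      gone <- FALSE
      for (S in sets) {
        r <- sysgen::partial_correlation(corr, i, j, S)
        if (!sysgen::ci_test_gauss(r, n, sz, alpha)$reject) { gone <- TRUE; break }
      }
      if (gone) { amat[i, j] <- amat[j, i] <- FALSE; break }
    }
  }
  amat
}

# a causal_graph built directly from a directed edge list (for KDA tests)
graph_from_edges <- function(edges, nodes) {
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) amat[edges$from[r], edges$to[r]] <- TRUE
  structure(list(amat = amat, nodes = sort(nodes), sepsets = list()),
            class = "causal_graph")
}

# adjusted Rand index between two label vectors (closed form over the
# pair-count contingency table) — independent of mclust
ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  n <- length(a)
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small default bundle for fast tests
small_config <- function(seed = 7) {
  sysgen::sim_config(n_samples = 120L, n_genes = 260L,
                     module_sizes = rep(40L, 3L), n_datasets = 2L,
                     seed = seed)
}
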