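#' Partial correlation from a correlation matrix
#'
#' Partial correlation of variables i and j given the set S, computed by
#' inverting the correlation submatrix over {i, j} union S:
#' r = -P_ij / sqrt(P_ii * P_jj) with P the inverse.
#'
#' @param corr Correlation matrix (named or indexed).
#' @param i,j Variable indices or names.
#' @param S Conditioning set (possibly empty).
#' @return Partial correlation.
#' @export
partial_correlation <- function(corr, i, j, S = character()) {
  idx <- c(i, j, S)
  m <- corr[idx, idx, drop = FALSE]
  p <- tryCatch(solve(m), error = function(e)
    stop("singular correlation submatrix for {", paste(idx, collapse = ","), "}"))
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

#' Gaussian conditional-independence test (Fisher z)
#'
#' z = atanh(r); the statistic sqrt(n - |S| - 3) * |z| is referred to the
#' standard normal, two-sided. Independence is rejected when p < alpha.
#'
#' @param r_partial Partial correlation.
#' @param n Sample size.
#' @param s_size Size of the conditioning set.
#' @param alpha Significance level, default 0.01.
#' @return List: p, reject.
#' @export
ci_test_gauss <- function(r_partial, n, s_size, alpha = 0.01) {
  if (n - s_size - 3 <= 0) stop("need n - |S| - 3 > 0")
  if (abs(r_partial) >= 1) {
    warning("|partial correlation| >= 1; p set to 0")
    return(list(p = 0, reject = TRUE))
  }
  z <- atanh(r_partial)
  stat <- sqrt(n - s_size - 3) * abs(z)
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  list(p = p, reject = p < alpha)
}

sepset_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' PC-algorithm skeleton (stable variant)
#'
#' Starts from the complete undirected graph over the genes and removes the
#' edge (i, j) whenever some conditioning set S of size l, drawn from the
#' neighbourhood of i or of j (excluding the other endpoint), fails to
#' reject conditional independence at level `alpha`. Levels l = 0, 1, 2, ...
#' are processed with the adjacency sets snapshotted per level
#' (order-independent "stable" PC); nodes and candidate sets are iterated in
#' sorted id order, so the output is deterministic.
#'
#' @param expr Genes x samples matrix (finite values).
#' @param alpha CI-test level, default 0.01.
#' @param max_level Optional cap on the conditioning-set size.
#' @return List of class `pc_skeleton`: `amat` (symmetric logical adjacency),
#'   `sepsets` (named list keyed "i|j"), `nodes`, `n`.
#' @export
pc_skeleton <- function(expr, alpha = 0.01, max_level = Inf) {
  if (!all(is.finite(expr))) stop("expression contains non-finite values")
  nodes <- sort(rownames(expr))
  expr <- expr[nodes, , drop = FALSE]
  n <- ncol(expr)
  corr <- stats::cor(t(expr))
  p <- length(nodes)
  amat <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(amat) <- FALSE
  sepsets <- list()

  l <- 0L
  repeat {
    if (n - l - 3 <= 0) break
    snapshot <- amat
    degrees <- rowSums(snapshot)
    if (all(degrees - 1 < l) || l > max_level) break
    for (i in nodes) {
      for (j in nodes[nodes > i]) {
        if (!amat[i, j]) next
        removed <- FALSE
        for (side in list(c(i, j), c(j, i))) {
          cand <- sort(setdiff(nodes[snapshot[side[1], ]], side[2]))
          if (length(cand) < l) next
          sets <- if (l == 0) list(character()) else
            utils::combn(cand, l, simplify = FALSE)
          for (S in sets) {
            r <- partial_correlation(corr, i, j, S)
            if (!ci_test_gauss(r, n, l, alpha)$reject) {
              amat[i, j] <- amat[j, i] <- FALSE
              sepsets[[sepset_key(i, j)]] <- S
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
    }
    l <- l + 1L
  }
  structure(list(amat = amat, sepsets = sepsets, nodes = nodes, n = n),
            class = "pc_skeleton")
}

#' Orient the skeleton into a CPDAG
#'
#' Orients v-structures i -> k <- j for every nonadjacent pair (i, j) with a
#' common neighbour k not contained in their separating set, then applies
#' Meek rules 1-3 to closure. Remaining edges stay undirected. The result is
#' the completed partially directed acyclic graph (Markov equivalence
#' class).
#'
#' @param skeleton A [pc_skeleton()] result.
#' @return Object of class `causal_graph`: `amat` (amat[i,j] TRUE with
#'   amat[j,i] FALSE means i -> j; both TRUE means undirected), `nodes`,
#'   `sepsets`.
#' @export
orient_edges <- function(skeleton) {
  nodes <- skeleton$nodes
  g <- skeleton$amat                      # symmetric at entry
  sep <- skeleton$sepsets

  directed <- function(a, b) g[a, b] && !g[b, a]
  undirected <- function(a, b) g[a, b] && g[b, a]
  adjacent <- function(a, b) g[a, b] || g[b, a]

  # v-structures
  for (k in nodes) {
    nb <- nodes[g[, k] & g[k, ]]
    if (length(nb) < 2) next
    for (i in nb) {
      for (j in nb[nb > i]) {
        if (adjacent(i, j)) next
        S <- sep[[sepset_key(i, j)]]
        if (!is.null(S) && k %in% S) next
        # orient i -> k and j -> k unless already oriented away from k
        if (undirected(i, k)) g[k, i] <- FALSE
        if (undirected(j, k)) g[k, j] <- FALSE
      }
    }
  }

  # Meek rules to closure
  repeat {
    changed <- FALSE
    for (a in nodes) for (b in nodes) {
      if (a == b || !undirected(a, b)) next
      # R1: c -> a, a - b, c not adjacent to b  =>  a -> b
      for (cc in nodes[g[, a] & !g[a, ]]) {
        if (!adjacent(cc, b)) { g[b, a] <- FALSE; changed <- TRUE; break }
      }
      if (!undirected(a, b)) next
      # R2: a -> c -> b with a - b  =>  a -> b
      for (cc in nodes) {
        if (cc != a && cc != b && directed(a, cc) && directed(cc, b)) {
          g[b, a] <- FALSE; changed <- TRUE; break
        }
      }
      if (!undirected(a, b)) next
      # R3: a - c -> b, a - d -> b, c,d nonadjacent  =>  a -> b
      cand <- nodes[vapply(nodes, function(cc)
        cc != a && cc != b && undirected(a, cc) && directed(cc, b), logical(1))]
      if (length(cand) >= 2) {
        done <- FALSE
        for (cc in cand) {
          for (dd in cand[cand > cc]) {
            if (!adjacent(cc, dd)) {
              g[b, a] <- FALSE; changed <- TRUE; done <- TRUE; break
            }
          }
          if (done) break
        }
      }
    }
    if (!changed) break
  }
  structure(list(amat = g, nodes = nodes, sepsets = sep),
            class = "causal_graph")
}

#' Learn a CPDAG with the PC algorithm
#'
#' Convenience wrapper: [pc_skeleton()] followed by [orient_edges()].
#'
#' @inheritParams pc_skeleton
#' @return A `causal_graph`.
#' @export
pc_algorithm <- function(expr, alpha = 0.01, max_level = Inf) {
  orient_edges(pc_skeleton(expr, alpha = alpha, max_level = max_level))
}

#' Edge list of a causal graph
#'
#' @param graph A `causal_graph`.
#' @return Data frame: from, to, type ("directed"/"undirected"); undirected
#'   edges are reported once with from < to.
#' @export
causal_edges <- function(graph) {
  g <- graph$amat
  nodes <- graph$nodes
  rows <- list()
  for (a in nodes) for (b in nodes) {
    if (g[a, b] && !g[b, a])
      rows[[length(rows) + 1]] <- data.frame(from = a, to = b,
                                             type = "directed")
    else if (a < b && g[a, b] && g[b, a])
      rows[[length(rows) + 1]] <- data.frame(from = a, to = b,
                                             type = "undirected")
  }
  if (length(rows) == 0)
    return(data.frame(from = character(), to = character(),
                      type = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Size of the h-layer downstream neighbourhood
#'
#' Number of distinct nodes reachable from `node` through directed edges in
#' at most `h` steps, excluding the node itself. Undirected CPDAG edges are
#' not traversed.
#'
#' @param graph A `causal_graph`.
#' @param node Node id.
#' @param h Depth, >= 1.
#' @return Integer count.
#' @export
hln_size <- function(graph, node, h = 3L) {
  stopifnot(h >= 1)
  g <- graph$amat
  dir_children <- function(v) graph$nodes[g[v, ] & !g[, v]]
  frontier <- node
  seen <- character()
  for (step in seq_len(h)) {
    nxt <- unique(unlist(lapply(frontier, dir_children)))
    nxt <- setdiff(nxt, c(seen, node))
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen)
}

#' Key driver analysis of a module subnetwork
#'
#' Restricts the causal graph to the module genes, computes for every node
#' the size mu of its h-layer downstream neighbourhood and its directed
#' out-degree d, and nominates causal regulators (mu > mean(mu) + sd(mu))
#' and, among those, key drivers (d > mean(d) + 2 * sd(d)). Sample (n - 1)
#' standard deviations throughout; only directed edges count.
#'
#' @param graph A `causal_graph`.
#' @param module_genes Gene ids defining the module (genes absent from the
#'   graph are dropped with a warning).
#' @param h Neighbourhood depth, default 3.
#' @return List of class `kda_result`: `mu`, `out_degree` (named vectors),
#'   `mu_threshold`, `degree_threshold`, `causal_regulators`, `key_drivers`.
#' @export
key_driver_analysis <- function(graph, module_genes, h = 3L) {
  missing_genes <- setdiff(module_genes, graph$nodes)
  if (length(missing_genes) > 0)
    warning("dropping ", length(missing_genes),
            " module gene(s) absent from the graph")
  keep <- intersect(graph$nodes, module_genes)
  if (length(keep) < 3) stop("module subnetwork has fewer than 3 nodes")
  sub <- structure(list(amat = graph$amat[keep, keep, drop = FALSE],
                        nodes = sort(keep), sepsets = list()),
                   class = "causal_graph")
  mu <- vapply(sub$nodes, function(v) hln_size(sub, v, h), numeric(1))
  dd <- vapply(sub$nodes, function(v)
    sum(sub$amat[v, ] & !sub$amat[, v]), numeric(1))
  mu_thr <- mean(mu) + stats::sd(mu)
  d_thr <- mean(dd) + 2 * stats::sd(dd)
  regulators <- sub$nodes[mu > mu_thr]
  drivers <- intersect(regulators, sub$nodes[dd > d_thr])
  structure(list(mu = mu, out_degree = dd, mu_threshold = mu_thr,
                 degree_threshold = d_thr, h = h,
                 causal_regulators = regulators, key_drivers = drivers),
            class = "kda_result")
}
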