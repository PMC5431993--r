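#' Moderated-t differential expression for a two-group contrast
#'
#' Fits a per-gene linear model of expression on the group indicator plus
#' optional covariates and computes empirical-Bayes moderated t statistics:
#' per-gene residual variances are shrunk toward a common prior estimated by
#' moment-matching a scaled F distribution to the variance ensemble, and the
#' t statistic uses the shrunk variance with augmented degrees of freedom
#' (limma's lmFit/eBayes machinery).
#'
#' @param expr Genes x samples matrix.
#' @param group 0/1 (or two-level factor) vector, one entry per sample.
#' @param covariates Optional data frame of per-sample covariates (e.g.
#'   age).
#' @return Data frame: gene_id, logFC, t, p, fdr, s2_post, df_total.
#' @export
moderated_t <- function(expr, group, covariates = NULL) {
  group <- as.numeric(as.factor(group)) - 1
  if (length(unique(group)) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 2) stop("need >= 2 samples per group")
  dat <- data.frame(group = group)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  design <- stats::model.matrix(~ ., data = dat)
  fit <- limma::eBayes(limma::lmFit(expr, design))
  ci <- which(colnames(design) == "group")
  data.frame(gene_id = rownames(expr),
             logFC = fit$coefficients[, ci],
             t = fit$t[, ci],
             p = fit$p.value[, ci],
             fdr = stats::p.adjust(fit$p.value[, ci], method = "BH"),
             s2_post = fit$s2.post,
             df_total = fit$df.total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Moderated-F test over a set of contrasts
#'
#' Tests, per gene, whether all supplied contrasts of the design
#' coefficients are simultaneously zero, using the empirical-Bayes shrunk
#' variance (moderated F). Used for multi-time-point and group-by-time
#' analyses.
#'
#' @param expr Genes x samples matrix.
#' @param design Full-rank design matrix (samples x coefficients).
#' @param contrasts Coefficients x contrasts matrix.
#' @return Data frame: gene_id, F, p, fdr.
#' @export
moderated_f_contrasts <- function(expr, design, contrasts) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is rank-deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- limma::lmFit(expr, design)
  fit <- limma::eBayes(limma::contrasts.fit(fit, contrasts))
  data.frame(gene_id = rownames(expr),
             F = fit$F, p = fit$F.p.value,
             fdr = stats::p.adjust(fit$F.p.value, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold change between two conditions on the natural scale
#'
#' FC = 2^(mean_log2_A - mean_log2_B). The input must be declared log2.
#'
#' @param expr Genes x samples matrix.
#' @param condition Per-sample condition labels.
#' @param pair Length-2 character: c(A, B); the ratio is A over B.
#' @param scale Must be "log2" (a guard against linear-scale input).
#' @return Named per-gene fold-change vector.
#' @export
fold_change <- function(expr, condition, pair, scale = c("log2")) {
  scale <- match.arg(scale)
  stopifnot(length(pair) == 2, all(pair %in% condition))
  ma <- rowMeans(expr[, condition == pair[1], drop = FALSE])
  mb <- rowMeans(expr[, condition == pair[2], drop = FALSE])
  2^(ma - mb)
}

#' Combine p-values across studies by Fisher's method
#'
#' chi2 = -2 * sum(ln p_i), referred to a chi-squared distribution with 2k
#' degrees of freedom where k counts the studies actually contributing (NA
#' entries, e.g. genes unmeasured in a study, are dropped and k reduced).
#'
#' @param p_list Numeric p-values in (0, 1]; NA allowed (dropped).
#' @return List: chi2, df, p, k.
#' @export
fisher_combine <- function(p_list) {
  p <- p_list[!is.na(p_list)]
  if (length(p) == 0) stop("no non-missing p-values")
  if (any(p <= 0)) stop("p-value of 0 cannot be combined; clamp upstream")
  if (any(p > 1)) stop("p-values must be in (0, 1]")
  chi2 <- -2 * sum(log(p))
  k <- length(p)
  list(chi2 = chi2, df = 2 * k,
       p = stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE), k = k)
}

#' P-value of a Fisher combined statistic
#'
#' Upper tail of the chi-squared distribution with 2k degrees of freedom;
#' useful for recomputing a combined p from a reported statistic.
#'
#' @param chi2 Fisher combined statistic.
#' @param k Number of combined studies.
#' @return p-value.
#' @export
fisher_pvalue <- function(chi2, k) {
  stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE)
}

#' Standardized mean difference (Hedges g) and its variance
#'
#' Pooled-SD standardized difference of group A minus group B with the
#' small-sample correction J = 1 - 3 / (4 * (nA + nB - 2) - 1); sampling
#' variance (nA + nB) / (nA * nB) + g^2 / (2 * (nA + nB)).
#'
#' @param group_a,group_b Numeric vectors (each length >= 2).
#' @return List: g, var_g, nA, nB.
#' @export
smd <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (na + nb - 2) - 1)
  g <- J * d
  list(g = g, var_g = (na + nb) / (na * nb) + g^2 / (2 * (na + nb)),
       nA = na, nB = nb)
}

#' Between-study heterogeneity: Cochran's Q and I-squared
#'
#' Q = sum w * (g - g_fixed)^2 with inverse-variance weights w, referred to
#' chi-squared with k - 1 df; I2 = max(0, (Q - (k - 1)) / Q) * 100.
#'
#' @param effects Per-study effect sizes (length k >= 2).
#' @param variances Per-study sampling variances (> 0).
#' @return List: Q, I2 (percent), Q_p.
#' @export
heterogeneity <- function(effects, variances) {
  k <- length(effects)
  stopifnot(k >= 2, length(variances) == k)
  if (any(variances <= 0)) stop("variances must be positive")
  w <- 1 / variances
  g_fixed <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - g_fixed)^2)
  list(Q = Q,
       I2 = max(0, (Q - (k - 1)) / Q) * 100,
       Q_p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' Pool effect sizes across studies
#'
#' Fixed-effect model: inverse-variance weights. Random-effects model:
#' DerSimonian-Laird tau-squared added to every study variance. The "auto"
#' rule selects random effects when the heterogeneity Q test has p < 0.05 or
#' I2 > 50%, fixed effects otherwise.
#'
#' @param effects,variances Per-study effect sizes and variances (k >= 2).
#' @param rule "auto" (default), "fixed" or "random".
#' @return List: model, pooled, se, ci_low, ci_high, z, p, tau2, Q, I2, Q_p.
#' @export
pooled_effect <- function(effects, variances, rule = c("auto", "fixed", "random")) {
  rule <- match.arg(rule)
  k <- length(effects)
  stopifnot(k >= 2)
  het <- heterogeneity(effects, variances)
  model <- switch(rule,
    fixed = "fixed", random = "random",
    auto = if (het$Q_p < 0.05 || het$I2 > 50) "random" else "fixed")
  w <- 1 / variances
  tau2 <- 0
  if (model == "random") {
    tau2 <- max(0, (het$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (variances + tau2)
  }
  pooled <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- pooled / se
  list(model = model, pooled = pooled, se = se,
       ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
       z = z, p = 2 * stats::pnorm(-abs(z)), tau2 = tau2,
       Q = het$Q, I2 = het$I2, Q_p = het$Q_p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; the input
#' order is preserved.
#'
#' @param p_list Numeric p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_list) {
  stats::p.adjust(p_list, method = "BH")
}

# per-gene SMDs and pooled z across a study collection
pooled_z_for_gene <- function(studies, gene, groups = NULL, rule = "auto") {
  eff <- c(); v <- c()
  for (s in seq_along(studies)) {
    st <- studies[[s]]
    if (!gene %in% rownames(st$expression)) next
    grp <- if (is.null(groups)) st$group else groups[[s]]
    x <- st$expression[gene, ]
    res <- smd(x[grp == 1], x[grp == 0])
    eff <- c(eff, res$g); v <- c(v, res$var_g)
  }
  if (length(eff) < 2) return(NA_real_)
  pooled_effect(eff, v, rule = rule)$z
}

#' Permutation p-value for a gene's pooled effect
#'
#' Permutes the group labels within each study, recomputes the pooled SMD z
#' statistic each time, and returns
#' perm_p = (1 + #{|z_b| >= |z_obs|}) / (B + 1).
#'
#' @param studies A `study_collection` (list of `expression` + `group`).
#' @param gene Gene id.
#' @param B Number of permutations, default 1000.
#' @param seed Integer seed.
#' @param rule Pooling rule forwarded to [pooled_effect()].
#' @return Permutation p-value.
#' @export
permutation_p <- function(studies, gene, B = 1000L, seed = 1L, rule = "auto") {
  z_obs <- pooled_z_for_gene(studies, gene, rule = rule)
  if (is.na(z_obs)) stop("gene measured in fewer than 2 studies")
  set.seed(seed)
  z_perm <- vapply(seq_len(B), function(b) {
    groups <- lapply(studies, function(st) sample(st$group))
    pooled_z_for_gene(studies, gene, groups = groups, rule = rule)
  }, numeric(1))
  (1 + sum(abs(z_perm) >= abs(z_obs), na.rm = TRUE)) / (B + 1)
}

#' Full per-gene meta-analysis across a study collection
#'
#' Runs moderated-t differential expression within every study, combines the
#' per-study p-values by Fisher's method (per-gene k counts the studies in
#' which the gene is measured), pools Hedges-g standardized mean differences
#' (obese minus non-obese) under the auto fixed/random rule, and optionally
#' attaches permutation p-values. Both p-value families are BH-adjusted.
#'
#' @param studies A `study_collection`.
#' @param B Permutations per gene for the permutation p (0 disables).
#' @param seed Integer seed for the permutation stage.
#' @return Data frame, one row per gene: fisher_chi2, fisher_k, fisher_p,
#'   fisher_fdr, smd (pooled), se, ci_low, ci_high, z, model, Q, I2, Q_p, p,
#'   fdr, and perm_p/perm_fdr when B > 0.
#' @export
meta_analyze <- function(studies, B = 0L, seed = 1L) {
  de <- lapply(studies, function(st) moderated_t(st$expression, st$group))
  genes <- sort(unique(unlist(lapply(de, `[[`, "gene_id"))))
  p_mat <- sapply(de, function(d) d$p[match(genes, d$gene_id)])
  rownames(p_mat) <- genes

  rows <- lapply(genes, function(g) {
    fc <- fisher_combine(p_mat[g, ])
    eff <- c(); v <- c()
    for (st in studies) {
      if (!g %in% rownames(st$expression)) next
      x <- st$expression[g, ]
      res <- smd(x[st$group == 1], x[st$group == 0])
      eff <- c(eff, res$g); v <- c(v, res$var_g)
    }
    pe <- pooled_effect(eff, v, rule = "auto")
    data.frame(gene_id = g, fisher_chi2 = fc$chi2, fisher_k = fc$k,
               fisher_p = fc$p, smd = pe$pooled, se = pe$se,
               ci_low = pe$ci_low, ci_high = pe$ci_high, z = pe$z,
               model = pe$model, Q = pe$Q, I2 = pe$I2, Q_p = pe$Q_p,
               p = pe$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fisher_fdr <- bh_fdr(out$fisher_p)
  out$fdr <- bh_fdr(out$p)
  if (B > 0) {
    out$perm_p <- vapply(seq_along(out$gene_id), function(i)
      permutation_p(studies, out$gene_id[i], B = B, seed = seed + i),
      numeric(1))
    out$perm_fdr <- bh_fdr(out$perm_p)
  }
  rownames(out) <- NULL
  out
}
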