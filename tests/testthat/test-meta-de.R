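test_that("moderated t shrinks ordinary t by the variance ratio and finds planted effects", {
  set.seed(60)
  n <- 40
  group <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:n)))
  res <- moderated_t(x, group)

  # identity linking moderated and ordinary t via the shrunk variance
  ord <- t(apply(x, 1, function(row) {
    fit <- summary(lm(row ~ group))$coefficients
    c(t = fit["group", "t value"], s2 = summary(lm(row ~ group))$sigma^2)
  }))
  expect_equal(res$t, ord[, "t"] * sqrt(ord[, "s2"] / res$s2_post),
               tolerance = 1e-8, ignore_attr = TRUE)

  # zero-difference, near-zero-noise genes give t ~ 0, p ~ 1
  x0 <- x
  x0[1, ] <- rep(c(1, 2), n / 2) + rnorm(n, sd = 1e-6)
  res0 <- moderated_t(x0, group)
  expect_lt(abs(res0$t[1]), 0.5)
  expect_gt(res0$p[1], 0.5)

  # planted delta = 1 in 50 of 500 genes, 25/group at sd 1
  set.seed(61)
  n2 <- 100
  g2 <- rep(0:1, each = 50)
  y <- matrix(rnorm(500 * n2), 500, n2,
              dimnames = list(sprintf("g%d", 1:500), NULL))
  y[1:50, g2 == 1] <- y[1:50, g2 == 1] + 1
  res2 <- moderated_t(y, g2)
  expect_gte(mean(res2$fdr[1:50] < 0.05), 0.9)
  expect_lte(mean(res2$fdr[51:500] < 0.05), 0.02)
  expect_true(all(res2$fdr >= res2$p))

  expect_error(moderated_t(x, rep(1, n)), "two levels")
})

test_that("moderated F is calibrated, equals t^2 for one contrast, and ranks planted trends", {
  set.seed(62)
  n <- 30
  time <- factor(rep(c("t0", "t1", "t2"), each = n / 3))
  design <- model.matrix(~ 0 + time)
  contrasts <- cbind(t1_vs_t0 = c(-1, 1, 0), t2_vs_t0 = c(-1, 0, 1))
  x <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("g%d", 1:1000), NULL))
  null_res <- moderated_f_contrasts(x, design, contrasts)
  expect_gt(ks.test(null_res$p, "punif")$p.value, 0.01)

  single <- moderated_f_contrasts(x, design, contrasts[, 1, drop = FALSE])
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(x, design), contrasts[, 1, drop = FALSE]))
  expect_equal(single$F, unname(fit$t[, 1]^2), tolerance = 1e-10)

  # planted linear time trend in the first 50 genes
  y <- x
  trend <- rep(c(0, 1, 2), each = n / 3)
  y[1:50, ] <- y[1:50, ] + matrix(trend, 50, n, byrow = TRUE)
  res <- moderated_f_contrasts(y, design, contrasts)
  lab <- c(rep(1, 50), rep(0, 950))
  auc <- (mean(rank(res$F)[lab == 1]) - (50 + 1) / 2) / 950
  expect_gte(auc, 0.9)

  bad <- cbind(design, dup = design[, 1])
  expect_error(moderated_f_contrasts(x, bad, contrasts), "aliased")
})

test_that("fold change is the ratio of anti-logged group means", {
  x <- matrix(c(5, 5, 5, 5,
                6, 6, 5, 5,
                5.485, 5.485, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("flat", "double", "gpd"), NULL))
  cond <- c("after", "after", "before", "before")
  fc <- fold_change(x, cond, c("after", "before"))
  expect_equal(unname(fc["flat"]), 1)
  expect_equal(unname(fc["double"]), 2)
  expect_equal(unname(fc["gpd"]), 1.40, tolerance = 0.01)
  expect_error(fold_change(x, cond, c("after", "before"), scale = "linear"))
})

test_that("Fisher combination matches the chi-squared tail and handles missing studies", {
  expect_equal(fisher_combine(rep(1, 5))$chi2, 0)
  expect_equal(fisher_combine(rep(1, 5))$p, 1)
  expect_equal(fisher_combine(rep(0.05, 5))$chi2, -2 * 5 * log(0.05))
  expect_equal(fisher_combine(rep(0.05, 5))$chi2, 29.957, tolerance = 1e-3)

  with_na <- fisher_combine(c(0.01, 0.02, NA, 0.5))
  expect_equal(with_na$k, 3)
  expect_equal(with_na$df, 6)
  expect_equal(with_na$p,
               pchisq(-2 * sum(log(c(0.01, 0.02, 0.5))), 6, lower.tail = FALSE))

  # strictly decreasing in chi2 at fixed k
  p_seq <- sapply(c(10, 20, 40), function(c2)
    pchisq(c2, 10, lower.tail = FALSE))
  expect_true(all(diff(p_seq) < 0))
  expect_error(fisher_combine(c(0.5, 0)), "clamp")
})

test_that("Hedges g matches the hand-computed example and its small-sample correction", {
  ex <- smd(c(0, 1, 2), c(2, 3, 4))
  expect_equal(ex$g, -1.6)                 # d = -2, J = 0.8
  expect_equal(ex$var_g, 6 / 9 + 1.6^2 / 12)

  same <- smd(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$g, 0)
  expect_error(smd(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("heterogeneity statistics match their definitions", {
  eq <- heterogeneity(rep(0.5, 4), rep(1, 4))
  expect_equal(eq$Q, 0)
  expect_equal(eq$I2, 0)

  a <- sqrt(2.5)
  h <- heterogeneity(c(a, -a, a, -a, 0), rep(1, 5))   # Q = 10 exactly
  expect_equal(h$Q, 10)
  expect_equal(h$I2, 60)                               # (10 - 4) / 10
  expect_equal(h$Q_p, pchisq(10, 4, lower.tail = FALSE))

  low <- heterogeneity(c(0.5, 0.51), c(1, 1))          # Q < k - 1: floored
  expect_equal(low$I2, 0)
  expect_error(heterogeneity(c(1, 2), c(1, -1)), "positive")
})

test_that("effect pooling follows inverse-variance algebra and the auto rule", {
  eq <- pooled_effect(rep(0.5, 3), rep(0.2, 3), rule = "fixed")
  expect_equal(eq$pooled, 0.5)
  expect_equal(pooled_effect(rep(0.5, 3), rep(0.2, 3), rule = "random")$pooled,
               0.5)

  fx <- pooled_effect(c(0, 1), c(1, 1), rule = "fixed")
  expect_equal(fx$pooled, 0.5)
  expect_equal(fx$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(fx$ci_low, 0.5 - 1.96 * sqrt(0.5))
  expect_equal((fx$ci_low + fx$ci_high) / 2, fx$pooled)  # CI symmetric on SMD

  # auto -> random on Q_p < 0.05 even with I2 <= 50 (the "or" rule)
  set.seed(63)
  k <- 51
  e <- scale(rnorm(k))[, 1] * sqrt(70 / (k - 1))   # Q = 70, df = 50
  auto <- pooled_effect(e, rep(1, k), rule = "auto")
  expect_lt(auto$Q_p, 0.05)
  expect_lte(auto$I2, 50)
  expect_identical(auto$model, "random")
  expect_gt(auto$tau2, 0)
  # random-effects CI contains the fixed-effects CI when tau2 > 0
  fx2 <- pooled_effect(e, rep(1, k), rule = "fixed")
  expect_lt(auto$ci_low, fx2$ci_low)
  expect_gt(auto$ci_high, fx2$ci_high)
  # pooled estimate within the effect range
  expect_true(auto$pooled >= min(e) && auto$pooled <= max(e))
})

test_that("pooling agrees with metafor as an independent oracle", {
  skip_if_not_installed("metafor")
  set.seed(64)
  e <- rnorm(6, sd = 0.6); v <- runif(6, 0.05, 0.3)
  fx <- pooled_effect(e, v, rule = "fixed")
  or_f <- metafor::rma(yi = e, vi = v, method = "FE")
  expect_equal(fx$pooled, as.numeric(or_f$beta), tolerance = 1e-10)
  expect_equal(fx$se, or_f$se, tolerance = 1e-10)

  rd <- pooled_effect(e, v, rule = "random")
  or_r <- metafor::rma(yi = e, vi = v, method = "DL")
  expect_equal(rd$pooled, as.numeric(or_r$beta), tolerance = 1e-10)
  expect_equal(rd$se, or_r$se, tolerance = 1e-10)
  expect_equal(rd$tau2, or_r$tau2, tolerance = 1e-10)
  expect_equal(rd$Q, or_r$QE, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand example and a step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)

  step_up <- function(p) {           # independent implementation
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- rep(NA_real_, m)
    run_min <- Inf
    for (idx in seq_along(o)) {
      i <- o[idx]
      rank_i <- m - idx + 1
      run_min <- min(run_min, p[i] * m / rank_i)
      adj[i] <- min(run_min, 1)
    }
    adj
  }
  set.seed(65)
  for (rep in 1:10) {
    p <- runif(25)^2
    expect_equal(bh_fdr(p), step_up(p))
    expect_true(all(bh_fdr(p) >= p & bh_fdr(p) <= 1))
  }
})

test_that("permutation p-values hit the lower bound and reproduce under a seed", {
  cfg <- sim_config(n_samples = 60, n_genes = 5, module_sizes = 5L,
                    planted_smd = 3, n_datasets = 3, seed = 66)
  st <- simulate_study_collection(cfg)
  pp <- permutation_p(st, "gene_0001", B = 99, seed = 2)
  expect_equal(pp, 1 / 100)     # observed z beyond every permutation
  expect_identical(permutation_p(st, "gene_0001", B = 99, seed = 2), pp)
})

test_that("permutation p-values are calibrated under the null", {
  cfg <- sim_config(n_samples = 40, n_genes = 60, module_sizes = integer(0),
                    planted_smd = 0, n_datasets = 3, seed = 67)
  st <- simulate_study_collection(cfg)
  pp <- vapply(sprintf("gene_%04d", 1:60), function(g)
    permutation_p(st, g, B = 99, seed = 3), numeric(1))
  # permutation p-values live on a 1/(B+1) grid, hence the tie warning
  expect_gt(suppressWarnings(ks.test(pp, "punif"))$p.value, 0.01)
})

test_that("the full meta table is internally consistent", {
  cfg <- sim_config(n_samples = 80, n_genes = 40, module_sizes = 20L,
                    planted_smd = 1, n_datasets = 4, seed = 68)
  st <- simulate_study_collection(cfg)
  meta <- meta_analyze(st)
  expect_equal(nrow(meta), 40)
  expect_true(all(meta$fisher_k == 4))
  expect_equal((meta$ci_low + meta$ci_high) / 2, meta$smd, tolerance = 1e-12)
  expect_true(all(meta$fisher_fdr >= meta$fisher_p - 1e-15))
  expect_true(all(meta$I2 >= 0 & meta$I2 <= 100))
  expect_true(all(meta$model %in% c("fixed", "random")))
  planted <- sprintf("gene_%04d", 1:20)
  expect_lt(max(meta$smd[meta$gene_id %in% planted]), -0.5)
})
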