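test_that("soft-threshold adjacency matches the element-wise |cor|^beta oracle", {
  x <- matrix(c(1, 2, 4, 3, 5, 1, 0, 2, 4, 6), 2, 5, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  a <- adjacency(x, beta = 6)
  expect_equal(a$a["a", "b"], abs(cor(x["a", ], x["b", ]))^6)
  expect_equal(abs(-0.5)^6, 0.015625)  # the beta=6 halving example
  expect_equal(adjacency(rbind(x, c = x["a", ] * 2 + 1), beta = 4)$a["a", "c"], 1)

  set.seed(1)
  r <- matrix(rnorm(100), 5, 20, dimnames = list(letters[1:5], NULL))
  a2 <- adjacency(r, beta = 6)$a
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) if (i != j)
    oracle[i, j] <- abs(cor(r[i, ], r[j, ]))^6
  expect_equal(unname(a2), oracle, tolerance = 1e-12)

  cst <- r; cst["c", ] <- 7
  expect_error(adjacency(cst), "c")
})

test_that("scale-free fit index separates power-law from Gaussian connectivity", {
  set.seed(4)
  k_pl <- (1 - runif(1e4))^(-2)          # Pareto tail, p(k) ~ k^-1.5
  k_pl <- k_pl[k_pl < 1e3]
  expect_gte(scale_free_fit_index(k_pl), 0.8)

  k_gauss <- rnorm(1e4, mean = 50, sd = 2)
  expect_lt(scale_free_fit_index(k_gauss), 0.5)

  # exactly log-log-linear bin profile -> R^2 = 1
  k_exact <- rep(100 * (1:10), times = 2520 / (1:10))
  expect_equal(scale_free_fit_index(k_exact), 1, tolerance = 1e-10)

  expect_error(scale_free_fit_index(rep(3, 100)), "distinct")
})

test_that("soft-threshold selection returns the smallest qualifying power", {
  set.seed(5)
  cfg <- small_config(seed = 5)
  x <- simulate_modular_expression(cfg)$expression
  ps <- pick_soft_threshold(x, betas = 1:12)
  expect_gte(ps$fit$r2[ps$fit$beta == ps$beta], 0.8)
  earlier <- ps$fit$r2[ps$fit$beta < ps$beta]
  expect_true(all(is.na(earlier) | earlier < 0.8))
  # target 0 -> smallest candidate wins
  expect_equal(pick_soft_threshold(x, betas = 2:8, r2_target = 0)$beta, 2)
})

test_that("TOM matches hand evaluation and the triple-loop oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(tom(tri)), matrix(1, 3, 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(tom(path)[1, 3], 0.5)     # (1+0)/(min(1,1)+1-0)

  set.seed(6)
  for (rep in 1:10) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2; diag(a) <- 0
    t1 <- tom(a)
    t2 <- tom_brute(a)
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_true(all(t1 >= 0 & t1 <= 1))
  }
})

test_that("module detection separates planted blocks and leaves noise grey", {
  # two clean blocks
  a <- matrix(0.01, 60, 60,
              dimnames = list(sprintf("g%d", 1:60), sprintf("g%d", 1:60)))
  a[1:30, 1:30] <- 0.95
  a[31:60, 31:60] <- 0.95
  diag(a) <- 0
  labs <- cluster_modules(1 - tom(a), min_module_size = 10)
  truth <- rep(c("A", "B"), each = 30)
  expect_equal(ari(labs, truth), 1)
  expect_setequal(unique(labs), c("turquoise", "blue"))

  # pure noise stays unassigned
  set.seed(7)
  noise <- matrix(rnorm(100 * 200), 100, 200,
                  dimnames = list(sprintf("g%d", 1:100), NULL))
  labs0 <- cluster_modules(1 - tom(adjacency(noise)$a), min_module_size = 30,
                           expr = noise)
  expect_true(all(labs0 == "grey"))

  expect_error(cluster_modules(1 - tom(a), min_module_size = 2), ">= 3")
})

test_that("eigengenes summarize their module and respect the sign convention", {
  set.seed(8)
  v <- rnorm(50)
  x <- matrix(rep(v, 4), 4, 50, byrow = TRUE) +
    matrix(rnorm(200, sd = 1e-8), 4, 50)
  rownames(x) <- sprintf("g%d", 1:4); colnames(x) <- sprintf("s%d", 1:50)
  labs <- setNames(rep("turquoise", 4), rownames(x))
  me <- module_eigengenes(x, labs)[, "turquoise"]
  expect_equal(unname(me), as.numeric(scale(v)), tolerance = 1e-5)
  expect_equal(as.numeric(abs(cor(t(x), me))), rep(1, 4), tolerance = 1e-5)

  # negating all member rows leaves |cor| structure invariant
  me_neg <- module_eigengenes(-x, labs)[, "turquoise"]
  expect_equal(abs(cor(me, me_neg)), 1, tolerance = 1e-8)
  expect_gt(mean(cor(t(-x), me_neg)), 0)   # convention re-aligns

  # planted factor is recovered at default loadings
  cfg <- sim_config(n_samples = 150, n_genes = 40, module_sizes = 40L, seed = 9)
  sim <- simulate_modular_expression(cfg)
  labs2 <- setNames(rep("blue", 40), rownames(sim$expression))
  me2 <- module_eigengenes(sim$expression, labs2)[, "blue"]
  expect_gte(abs(cor(me2, sim$factors["mod1", ])), 0.9)
  # first-PC property: ME explains the largest single-component variance share
  sv <- svd(t(standardize_rows(sim$expression)))
  expect_equal(abs(cor(sv$u[, 1], me2)), 1, tolerance = 1e-8)
})

test_that("age-adjusted module-trait association is a partial correlation", {
  set.seed(10)
  n <- 200
  age <- runif(n, 30, 70)
  me <- rnorm(n)
  expect_equal(module_trait_association(me, me, age)$r, 1, tolerance = 1e-12)
  # a trait fully explained by age leaves only noise: partial r is a null
  # correlation at n = 200 (sd ~ 0.07), so a 3-sigma band applies
  expect_lt(abs(module_trait_association(me, age + rnorm(n, sd = 1e-8), age)$r),
            0.22)
  # planted partial correlation 0.5
  trait <- 0.8 * scale(age)[, 1] + 0.5 * me + sqrt(1 - 0.25) * rnorm(n)
  est <- module_trait_association(me, trait, age)
  expect_equal(est$r, 0.5, tolerance = 0.12)
  expect_equal(est$r_squared, est$r^2)
  expect_error(module_trait_association(me, rep(1, n), age), "variance")
})

test_that("gene significance reproduces the t-transform p-values", {
  # r = -0.23 at n = 199 (the discovery-cohort hub-gene case)
  set.seed(11)
  n <- 199
  # construct data with exact sample correlation via residual trick
  y <- rnorm(n)
  x <- rnorm(n)
  x <- resid(lm(x ~ y)); x <- x / sd(x)
  r_target <- -0.23
  z <- r_target * scale(y)[, 1] + sqrt(1 - r_target^2) * x
  expect_equal(cor(z, y), r_target, tolerance = 1e-10)
  gsr <- gene_significance(z, y)
  expect_equal(gsr$gs, 0.23, tolerance = 1e-10)
  expect_equal(gsr$p, 1.06e-3, tolerance = 0.03)

  # r = 0.5, n = 10 -> t = 1.633, p = 0.141 (df = 8)
  expect_equal(cor_pvalue(0.5, 10), 2 * pt(-0.5 * sqrt(8 / 0.75), 8))
  expect_equal(cor_pvalue(0.5, 10), 0.141, tolerance = 0.005)
  expect_equal(cor_pvalue(0, 50), 1)
  expect_error(gene_significance(rep(1, 20), rbinom(20, 1, 0.5)), "constant")
})

test_that("kME is reported for members and non-members with a null floor", {
  cfg <- sim_config(n_samples = 200, n_genes = 140, module_sizes = 40L,
                    seed = 12)
  sim <- simulate_modular_expression(cfg)
  labs <- setNames(ifelse(sim$truth$module == "mod1", "turquoise", "grey"),
                   sim$truth$gene_id)
  mes <- module_eigengenes(sim$expression, labs)
  mm <- module_membership(sim$expression, mes)
  expect_equal(dim(mm$kme), c(140L, 1L))   # non-members included, not masked
  members <- sim$truth$gene_id[sim$truth$module == "mod1"]
  noise <- setdiff(sim$truth$gene_id, members)
  expect_gt(mean(mm$kme[members, 1]), mean(mm$kme[noise, 1]))
  expect_lt(quantile(mm$kme[noise, 1], 0.95), 0.15)
  # gene identical to the eigengene
  x2 <- rbind(sim$expression, me_gene = mes[, 1])
  expect_equal(module_membership(x2, mes)$kme["me_gene", 1], 1,
               tolerance = 1e-12)
})

test_that("hub criteria are strict and the connectivity mode picks the top gene", {
  labs <- setNames(c(rep("turquoise", 3), "grey"), c("a", "b", "c", "d"))
  kme <- matrix(c(0.90, 0.80, 0.85, 0.1), ncol = 1,
                dimnames = list(c("a", "b", "c", "d"), "turquoise"))
  gs <- setNames(c(0.23, 0.5, 0.15, 0.9), c("a", "b", "c", "d"))
  hubs <- identify_hub_genes(labs, gs = gs, kme = kme)
  expect_identical(hubs$turquoise, "a")   # b fails strict kME, c fails GS

  # threshold degeneracy: zero cuts return all non-grey genes
  all_hubs <- identify_hub_genes(labs, gs = gs, kme = kme,
                                 mm_cut = 0, gs_cut = 0)
  expect_setequal(all_hubs$turquoise, c("a", "b", "c"))

  # hand-computed connectivity: B has the largest intramodular sum
  # (kA = 0.9 + 0.1 = 1.0, kB = 0.9 + 0.8 = 1.7, kC = 0.1 + 0.8 = 0.9)
  a <- matrix(c(0, .9, .1,
                .9, 0, .8,
                .1, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  labs2 <- setNames(rep("blue", 3), c("A", "B", "C"))
  expect_identical(identify_hub_genes(labs2, adj = a,
                                      mode = "max_connectivity")$blue, "B")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("g%d", 1:100)
  module <- universe[1:10]
  cat_map <- list(hit = c(universe[6:10], universe[50:54]),  # k=5, K=10
                  none = universe[90:95],                    # k=0
                  all = universe)
  res <- enrichment_test(module, cat_map, universe)
  hit <- res[res$category == "hit", ]
  expect_equal(hit$fold, 5.0)
  oracle <- sum(sapply(5:10, function(x)
    choose(10, x) * choose(90, 10 - x) / choose(100, 10)))
  expect_equal(hit$p, oracle, tolerance = 1e-12)
  expect_equal(res$fold[res$category == "none"], 0)
  expect_equal(res$p[res$category == "none"], 1)
  expect_equal(res$fold[res$category == "all"], 1)
  expect_equal(res$p[res$category == "all"], 1)
  expect_true(all(res$p_bonferroni >= res$p))
  expect_warning(enrichment_test(module, list(gone = "zz"), universe),
                 "skipped")
})
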