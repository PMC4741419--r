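test_that("single-feature MANOVA without covariates equals the pooled t-test", {
  set.seed(101)
  for (k in 1:10) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    y <- c(rnorm(n1, 0, 1), rnorm(n2, 0.4, 1))
    g <- rep(c("HC", "PATIENT"), c(n1, n2))
    mv <- manova_group_test(matrix(y, ncol = 1), g)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(mv$p_raw, tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give a zero statistic and p = 1", {
  set.seed(102)
  X1 <- matrix(rnorm(30), ncol = 3)
  X <- rbind(X1, X1)  # group 2 equals group 1 subject-for-subject
  g <- rep(c("HC", "PATIENT"), each = 10)
  mv <- manova_group_test(X, g)
  expect_lt(mv$statistic, 1e-12)
  expect_equal(mv$p_raw, 1, tolerance = 1e-10)
})

test_that("a large separation on one feature is detected multivariately", {
  set.seed(103)
  X <- cbind(c(rnorm(20), rnorm(20, 5)), rnorm(40), rnorm(40))
  g <- rep(c("HC", "PATIENT"), each = 20)
  mv <- manova_group_test(X, g)
  expect_lt(mv$p_raw, 1e-6)
})

test_that("MANOVA validates its design", {
  X <- matrix(rnorm(12), ncol = 3)
  expect_error(manova_group_test(X, rep(c("HC", "PATIENT"), c(1, 3))),
               "at least 3")
  g <- rep(c("HC", "PATIENT"), each = 10)
  cov_collinear <- data.frame(z = as.numeric(factor(g)))
  expect_error(manova_group_test(matrix(rnorm(60), ncol = 3), g, cov_collinear),
               "rank-deficient")
})

test_that("exhaustive permutation p equals full enumeration", {
  set.seed(104)
  for (k in 1:5) {
    x <- rnorm(6, sd = 2) + c(0, 0, 0, 1.5, 1.5, 1.5)
    g <- rep(c("HC", "PATIENT"), each = 3)
    res <- permutation_component_test(x, g)
    expect_true(res$exhaustive)
    expect_equal(res$n_perm_used, 20)
    expect_equal(res$p_raw, enumerate_perm_p(x, g), tolerance = 1e-12)
  }
})

test_that("permutation p-values respect the resolution floor and determinism", {
  set.seed(105)
  x <- c(rnorm(20), rnorm(20, 10))  # overwhelming separation
  g <- rep(c("HC", "PATIENT"), each = 20)
  res <- permutation_component_test(x, g, n_perm = 999, seed = 7)
  expect_false(res$exhaustive)
  expect_gte(res$p_raw, 1 / 1000)
  res2 <- permutation_component_test(x, g, n_perm = 999, seed = 7)
  expect_identical(res$p_raw, res2$p_raw)
})

test_that("permutation p is invariant to which group is called control", {
  set.seed(106)
  x <- rnorm(8) + rep(c(0, 1), each = 4)
  g <- rep(c("HC", "PATIENT"), each = 4)
  g_swapped <- rep(c("PATIENT", "HC"), each = 4)
  p1 <- permutation_component_test(x, g)$p_raw            # exhaustive
  p2 <- permutation_component_test(x, g_swapped)$p_raw
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("constant features yield p = 1 with a warning", {
  g <- rep(c("HC", "PATIENT"), each = 4)
  expect_warning(res <- permutation_component_test(rep(3, 8), g), "constant")
  expect_equal(res$p_raw, 1)
  expect_equal(res$statistic, 0)
})

test_that("covariate adjustment removes a pure covariate effect", {
  set.seed(107)
  n <- 40
  g <- rep(c("HC", "PATIENT"), each = n / 2)
  age <- c(rnorm(n / 2, 30, 5), rnorm(n / 2, 45, 5))  # confounded with group
  x <- 2 * age + rnorm(n, 0, 1)                        # feature driven by age only
  p_unadj <- permutation_component_test(x, g, n_perm = 999, seed = 1)$p_raw
  p_adj <- permutation_component_test(x, g, covariates = data.frame(age = age),
                                      n_perm = 999, seed = 1)$p_raw
  expect_lt(p_unadj, 0.01)   # the confound masquerades as a group effect
  expect_gt(p_adj, 0.05)     # adjustment removes it
})

test_that("global-mean test reduces to the classical t-test without covariates", {
  expect_equal(global_mean_test(c(1, 2, 3, 1, 2, 3),
                                rep(c("HC", "PATIENT"), each = 3))$p_raw, 1)
  set.seed(108)
  for (k in 1:5) {
    y <- rnorm(24, sd = 30) + rep(c(0, 15), each = 12)
    g <- rep(c("HC", "PATIENT"), each = 12)
    res <- global_mean_test(y, g)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
    expect_equal(abs(res$statistic), abs(tt$statistic[[1]]), tolerance = 1e-12)
  }
  g <- rep(c("HC", "PATIENT"), each = 5)
  expect_error(global_mean_test(rnorm(10), g,
                                data.frame(z = as.numeric(factor(g)))),
               "rank-deficient")
})

test_that("Bonferroni arithmetic, capping and identity", {
  expect_equal(correct_multiplicity(c(0.0004, 0.5, 0.01, 0.2), "bonferroni"),
               c(0.0016, 1, 0.04, 0.8))
  expect_equal(correct_multiplicity(0.3, "bonferroni"), 0.3)  # m = 1
  set.seed(109)
  p <- runif(6)
  expect_true(all(correct_multiplicity(p, "bonferroni") >= p))
  expect_error(correct_multiplicity(numeric(0), "bonferroni"), "empty")
})

test_that("max-statistic FWE is valid and less conservative than Bonferroni on correlated features", {
  set.seed(110)
  n <- 30; m <- 3
  g <- rep(c("HC", "PATIENT"), each = n / 2)
  # strongly correlated null features
  base <- rnorm(n)
  X <- sapply(1:m, function(j) base + rnorm(n, 0, 0.3))
  r <- apply(X, 2, function(v) v - mean(v))
  ps <- t1pve:::make_perm_sets(n, n / 2, 999)
  t_obs <- apply(r, 2, function(v) abs(t1pve:::pooled_t(v, g)))
  t_perm <- apply(r, 2, function(v) t1pve:::perm_abs_t(v, n / 2, n / 2, ps$idx))
  p_raw <- sapply(1:m, function(j)
    (1 + sum(t_perm[, j] >= t_obs[j] - 1e-12)) / (1 + nrow(t_perm)))
  p_fwe <- correct_multiplicity(p_raw, "max_stat_fwe",
                                perm_stats = t_perm, stat_obs = t_obs)
  p_bon <- correct_multiplicity(p_raw, "bonferroni")
  expect_true(all(p_fwe >= p_raw - 1e-12))
  expect_true(all(p_fwe <= 1))
  # averaged over the family, the max-statistic correction is tighter
  expect_lte(mean(p_fwe), mean(p_bon) + 1e-9)
})

test_that("run_comparison produces the full grid of tests deterministically", {
  set.seed(111)
  regions <- c("thalamus", "caudate")
  feats <- null_feature_table(24, regions)
  cohort <- null_cohort(24)
  cfg <- default_run_config()
  cfg$regions <- regions
  cfg$stats$n_perm <- 199
  res <- run_comparison(feats, cohort, cfg)
  expect_equal(nrow(res), length(regions) * 5)
  expect_equal(sort(unique(res$arm)),
               c("global_mean", "pv_component", "pv_manova"))
  expect_true(all(res$p_corrected >= res$p_raw - 1e-12))
  expect_true(all(res$p_raw > 0 & res$p_corrected <= 1))
  # determinism under the configured seed
  res2 <- run_comparison(feats, cohort, cfg)
  expect_identical(res$p_raw, res2$p_raw)
  # max-stat correction variant also runs end to end
  cfg$stats$correction <- "max_stat_fwe"
  res3 <- run_comparison(feats, cohort, cfg)
  comp <- res3[res3$arm == "pv_component", ]
  expect_true(all(comp$correction_method == "max_stat_fwe"))

  # single-subject group is rejected
  bad_cohort <- cohort
  bad_cohort$group <- c("HC", rep("PATIENT", 23))
  expect_error(run_comparison(feats, bad_cohort, cfg), "at least 3")
  # absent region is reported
  cfg$regions <- c("thalamus", "pallidum")
  expect_error(run_comparison(feats, cohort, cfg), "absent")
})
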