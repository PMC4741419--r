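test_that("concentration update is the clamped linear unmixing", {
  ti <- tissue_intensities(1350, 850)
  expect_equal(estimate_concentrations(1100, ti)$c_gm, 0.5)
  expect_equal(estimate_concentrations(c(1350, 850), ti)$c_gm, c(1, 0))
  # out-of-range voxels saturate
  expect_equal(estimate_concentrations(c(2000, 100), ti)$c_gm, c(1, 0))
  # intensity ordering is enforced at construction
  expect_error(tissue_intensities(1000, 1000), "mu_gm must exceed")
})

test_that("fixed-concentration intensity update solves the normal equations", {
  # pure-tissue voxels
  f <- estimate_tissue_intensities(c(900, 1400), c(0, 1))
  expect_equal(c(f$mu_gm, f$mu_wm, f$sigma), c(1400, 900, 0))
  # exactly collinear data
  f2 <- estimate_tissue_intensities(c(850, 1100, 1350), c(0, 0.5, 1))
  expect_equal(c(f2$mu_gm, f2$mu_wm), c(1350, 850))
  expect_lt(f2$sigma, 1e-9)
  # random instances against an independent lm() oracle
  set.seed(42)
  for (k in 1:10) {
    cc <- seq(0, 1, length.out = 50) + runif(50, -0.005, 0.005)
    cc <- pmin(1, pmax(0, cc))
    y <- mix_y(1400, 900, cc, noise_sd = 30)
    fit <- estimate_tissue_intensities(y, cc)
    oracle <- coef(lm(y ~ 0 + cbind(gm = cc, wm = 1 - cc)))
    expect_equal(fit$mu_gm, unname(oracle[1]), tolerance = 1e-9)
    expect_equal(fit$mu_wm, unname(oracle[2]), tolerance = 1e-9)
  }
  # rank-deficient design
  expect_error(estimate_tissue_intensities(c(1, 2, 3), c(0.4, 0.4, 0.4)),
               "degenerate")
})

test_that("mixture RSS is invariant under the tissue label swap", {
  set.seed(7)
  for (k in 1:25) {
    n <- sample(5:50, 1)
    cc <- runif(n)
    y <- rnorm(n, 1100, 150)
    mus <- sort(runif(2, 600, 1800))
    r1 <- pve_objective(y, cc, list(mu_gm = mus[2], mu_wm = mus[1]))
    r2 <- pve_objective(y, 1 - cc, list(mu_gm = mus[1], mu_wm = mus[2]))
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("noise-free alternating fit recovers the true intensities", {
  cc <- seq(0, 1, by = 0.1)
  fit <- fit_pve(mix_y(1400, 900, cc))
  expect_lt(abs(fit$intensities$mu_gm - 1400), 1e-3)
  expect_lt(abs(fit$intensities$mu_wm - 900), 1e-3)
  expect_lt(fit$intensities$sigma, 0.1)
  expect_equal(fit$n_iterations, 10)
  expect_length(fit$rss_trace, 10)
})

test_that("degenerate inputs raise non-identifiability errors", {
  expect_error(fit_pve(rep(1000, 50)), "single concentration")
  expect_error(fit_pve(c(1000, 1100)), "at least 3")
})

test_that("early stopping honours the tolerance and flags convergence", {
  set.seed(3)
  y <- mix_y(1400, 900, runif(200), noise_sd = 40)
  fit <- fit_pve(y, tol = 0.5)
  expect_true(fit$converged_early)
  expect_lt(fit$n_iterations, 10)
  expect_length(fit$rss_trace, fit$n_iterations)
  # default runs all iterations
  fit0 <- fit_pve(y)
  expect_false(fit0$converged_early)
  expect_equal(fit0$n_iterations, 10)
  # same final estimates either way
  expect_equal(fit$intensities$mu_gm, fit0$intensities$mu_gm, tolerance = 1e-6)
})

test_that("compiled likelihood matches the R reference implementation", {
  set.seed(5)
  y <- mix_y(1380, 880, runif(300), noise_sd = 60)
  lo <- min(y); hi <- max(y)
  for (k in 1:10) {
    par <- c(runif(1, 0, 80), runif(1, 0, 80), log(runif(1, 5, 120)))
    expect_equal(t1pve:::.pve_nll_cpp(par, y, lo, hi),
                 t1pve:::pve_nll(par, y, lo, hi), tolerance = 1e-8)
    expect_equal(t1pve:::.pve_nll_grad_cpp(par, y, lo, hi),
                 t1pve:::pve_nll_grad(par, y, lo, hi), tolerance = 1e-8)
  }
})

test_that("region fits equal vector fits and respect lesion exclusion", {
  ph <- generate_phantom(phantom_truth(noise_sd = 30, seed = 11))
  fit <- fit_region(ph$t1, ph$labels, "thalamus")
  idx <- which(ph$labels$labels == 1L)
  direct <- fit_pve(ph$t1$values[idx])
  expect_equal(fit$intensities$mu_gm, direct$intensities$mu_gm)
  expect_equal(fit$intensities$mu_wm, direct$intensities$mu_wm)
  expect_equal(fit$n_voxels, length(idx))

  # lesion voxels are removed before fitting: counts are a set difference
  les <- array(FALSE, dim = dim(ph$t1$values))
  les[idx[1:100]] <- TRUE
  fit_les <- fit_region(ph$t1, ph$labels, "thalamus",
                        lesions = binary_mask(les))
  expect_equal(fit_les$n_voxels, length(idx) - 100)

  expect_error(fit_region(ph$t1, ph$labels, "amygdala"), "not in label")
})

test_that("regions below the minimum voxel count are rejected", {
  tr <- tiny_region(mix_y(1400, 900, seq(0, 1, length.out = 10)))
  expect_error(fit_region(tr$t1, tr$labels, "thalamus"), "fewer than")
  # and fit fine when the configured minimum allows them
  fit <- fit_region(tr$t1, tr$labels, "thalamus",
                    config = list(min_voxels = 5))
  expect_lt(abs(fit$intensities$mu_gm - 1400), 1e-3)
})

test_that("non-finite voxels are dropped with a logged count", {
  vals <- mix_y(1400, 900, seq(0, 1, length.out = 40))
  vals[3] <- NA; vals[7] <- -5
  tr <- tiny_region(vals)
  expect_message(fit <- fit_region(tr$t1, tr$labels, "thalamus"),
                 "dropping 2")
  expect_equal(fit$n_voxels, 38)
})

test_that("concentration maps are written back into grid coordinates", {
  ph <- generate_phantom(phantom_truth(noise_sd = 0, seed = 2))
  fit <- fit_region(ph$t1, ph$labels, "caudate")
  cmap <- concentration_map(fit, ph$labels)
  expect_equal(dim(cmap$values), dim(ph$t1$values))
  inside <- cmap$values[fit$voxels]
  expect_true(all(inside >= 0 & inside <= 1))
  # noise-free fit reproduces the generator's concentrations
  expect_equal(inside, ph$concentrations$caudate, tolerance = 1e-6)
  expect_equal(sum(cmap$values != 0), sum(inside != 0))
})
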