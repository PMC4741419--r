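test_that("lesion exclusion is a set difference with the expected properties", {
  dims <- c(5, 5, 5)
  reg <- array(FALSE, dims); reg[1:10] <- TRUE
  les <- array(FALSE, dims); les[8:12] <- TRUE
  out <- exclude_lesions(binary_mask(reg), binary_mask(les))
  expect_equal(sum(out$mask), 7)

  empty <- binary_mask(array(FALSE, dims))
  expect_equal(exclude_lesions(binary_mask(reg), empty)$mask, reg)

  all_les <- binary_mask(array(TRUE, dims))
  expect_equal(sum(exclude_lesions(binary_mask(reg), all_les)$mask), 0)

  # monotone: growing the lesion never grows the remainder
  set.seed(2)
  l <- array(FALSE, dims)
  prev <- sum(reg)
  for (k in 1:20) {
    l[sample(125, 1)] <- TRUE
    now <- sum(exclude_lesions(binary_mask(reg), binary_mask(l))$mask)
    expect_lte(now, prev)
    prev <- now
  }

  bad <- binary_mask(array(FALSE, c(4, 4, 4)))
  expect_error(exclude_lesions(binary_mask(reg), bad), "same grid")
})

test_that("concentration ratio is the ratio of mean concentrations", {
  expect_equal(concentration_ratio(rep(0.5, 20)), 1)
  expect_equal(round(concentration_ratio(rep(0.383, 7)), 2), 0.62)
  expect_error(concentration_ratio(rep(1, 5)), "undefined")
  # voxel-order invariance and reciprocal under complementation
  set.seed(4)
  cc <- runif(50, 0.05, 0.95)
  expect_equal(concentration_ratio(cc), concentration_ratio(rev(cc)))
  expect_equal(concentration_ratio(1 - cc), 1 / concentration_ratio(cc))
})

test_that("global mean T1 averages masked voxels and is bounded by them", {
  dims <- c(4, 4, 4)
  vals <- array(1100, dims)
  m <- array(FALSE, dims); m[1:8] <- TRUE
  expect_equal(global_mean_t1(t1_volume(vals), binary_mask(m)), 1100)

  vals2 <- array(0, dims); vals2[1:2] <- c(1000, 1200)
  m2 <- array(FALSE, dims); m2[1:2] <- TRUE
  expect_equal(global_mean_t1(t1_volume(vals2), binary_mask(m2)), 1100)

  # 5-voxel toy with lesion exclusion, checked by hand:
  # region voxels 1..5 = (900, 1000, 1100, 1200, 1300), lesion on 4,5
  vals3 <- array(0, dims); vals3[1:5] <- c(900, 1000, 1100, 1200, 1300)
  reg <- array(FALSE, dims); reg[1:5] <- TRUE
  les <- array(FALSE, dims); les[4:5] <- TRUE
  nam <- exclude_lesions(binary_mask(reg), binary_mask(les))
  expect_equal(global_mean_t1(t1_volume(vals3), nam), (900 + 1000 + 1100) / 3)

  set.seed(5)
  vals4 <- array(runif(64, 700, 1700), dims)
  m4 <- array(runif(64) < 0.4, dims)
  mt <- global_mean_t1(t1_volume(vals4), binary_mask(m4))
  expect_gte(mt, min(vals4[m4])); expect_lte(mt, max(vals4[m4]))

  expect_error(global_mean_t1(t1_volume(vals), binary_mask(array(FALSE, dims))),
               "empty mask")
})

test_that("subject features pass through the region fits and flag failures", {
  # phantom with only two regions defined
  truth <- phantom_truth(intensities = list(thalamus = c(1400, 910),
                                            caudate = c(1420, 915)),
                         noise_sd = 20, seed = 21)
  ph <- generate_phantom(truth, subject_id = "subA")
  feats <- extract_subject_features(ph$t1, ph$labels)
  expect_equal(feats$subject_id, "subA")
  expect_true(all(is.finite(unlist(
    feats[paste0("thalamus_", c("mu_gm", "mu_wm", "ratio", "mean_t1"))]))))
  expect_true(all(is.na(unlist(
    feats[paste0("putamen_", c("mu_gm", "mu_wm", "ratio", "mean_t1"))]))))

  fit <- fit_region(ph$t1, ph$labels, "thalamus")
  expect_equal(feats$thalamus_mu_gm, fit$intensities$mu_gm)
  expect_equal(feats$thalamus_mu_wm, fit$intensities$mu_wm)
  expect_equal(feats$thalamus_ratio, concentration_ratio(fit$concentrations))
  expect_equal(feats$thalamus_n_voxels, fit$n_voxels)

  # a degenerate region yields missing values plus a log entry, not a crash
  flat <- ph
  idx <- which(ph$labels$labels == 2L)
  flat$t1$values[idx] <- 1000
  expect_message(
    f2 <- extract_subject_features(flat$t1, flat$labels,
                                   config = utils::modifyList(
                                     default_run_config(),
                                     list(regions = c("thalamus", "caudate")))),
    "skipped")
  expect_true(is.na(f2$caudate_mu_gm))
  expect_false(is.na(f2$thalamus_mu_gm))
})

test_that("cohort feature extraction works from disk and records failures", {
  spec <- cohort_spec(n_control = 1, n_patient = 1, dim = c(32, 32, 32),
                      noise_sd = 30, lesion_count = 1, lesion_radius = 1,
                      seed = 31)
  out <- file.path(tempfile(), "cohort")
  gen <- generate_cohort(spec, out_dir = out)
  cfg <- default_run_config()
  cfg$regions <- "thalamus"
  feats <- extract_cohort_features(gen$cohort, cfg)
  expect_equal(nrow(feats), 2)
  expect_true(all(is.finite(feats$thalamus_mu_gm)))

  # corrupt one subject's volume: that subject goes missing, the other stays
  bad <- gen$cohort
  bad$t1_path[1] <- file.path(out, "nope.nii.gz")
  expect_warning(f2 <- extract_cohort_features(bad, cfg), "failed")
  expect_true(is.na(f2$thalamus_mu_gm[1]))
  expect_false(is.na(f2$thalamus_mu_gm[2]))
})
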