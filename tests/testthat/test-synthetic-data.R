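# Generators: feature cohorts and lesion phantoms.

test_that("label prevalence matches the target under the null model", {
  co <- generate_feature_cohort(cohort_spec(
    n_patients = 10000, prevalence = 0.5, n_informative = 2, n_noise = 2,
    n_redundant_per_block = 0, effect_sizes = 0, seed = 11
  ))
  # binomial 99.9% band around 0.5 at n = 10000
  expect_lt(abs(mean(co$table$labels) - 0.5), 3.3 * 0.5 / sqrt(10000))

  # and with effects + intercept solving, at an asymmetric target
  co2 <- generate_feature_cohort(cohort_spec(
    n_patients = 10000, prevalence = 0.21, n_informative = 3, n_noise = 1,
    n_redundant_per_block = 0, effect_sizes = 1, seed = 12
  ))
  expect_lt(abs(mean(co2$table$labels) - 0.21),
            3.3 * sqrt(0.21 * 0.79 / 10000))
})

test_that("redundant copies are rank-correlated with their parent as designed", {
  co <- generate_feature_cohort(cohort_spec(
    n_patients = 150, prevalence = 0.4, n_informative = 3, n_noise = 2,
    n_redundant_per_block = 2, within_block_correlation = 1.0, seed = 5
  ))
  X <- co$table$X
  for (b in names(co$truth$blocks)) {
    for (child in co$truth$blocks[[b]]) {
      expect_equal(cor(X[, b], X[, child], method = "spearman"), 1)
    }
  }

  co2 <- generate_feature_cohort(cohort_spec(
    n_patients = 150, prevalence = 0.4, n_informative = 3, n_noise = 2,
    n_redundant_per_block = 2, within_block_correlation = 0.95, seed = 6
  ))
  X2 <- co2$table$X
  for (b in names(co2$truth$blocks)) {
    for (child in co2$truth$blocks[[b]]) {
      rho <- cor(X2[, b], X2[, child], method = "spearman")
      expect_gte(rho, 0.95)
      expect_lt(rho, 1)
    }
  }
})

test_that("noise features are uncorrelated with the labels in distribution", {
  co <- generate_feature_cohort(cohort_spec(
    n_patients = 4000, prevalence = 0.4, n_informative = 2, n_noise = 15,
    n_redundant_per_block = 0, effect_sizes = 1.5, seed = 21
  ))
  noise_cols <- grep("^noise_", colnames(co$table$X), value = TRUE)
  cors <- abs(cor(co$table$X[, noise_cols], co$table$labels))
  expect_lt(mean(cors), 0.05)
  inf_cors <- abs(cor(co$table$X[, co$truth$informative], co$table$labels))
  expect_gt(min(inf_cors), 0.2)
})

test_that("generators are pure functions of spec + seed", {
  sp <- cohort_spec(n_patients = 61, prevalence = 0.41, seed = 99)
  a <- generate_feature_cohort(sp)
  b <- generate_feature_cohort(sp)
  expect_identical(a, b)

  ps <- phantom_spec(seed = 42)
  expect_identical(generate_lesion_phantom(ps), generate_lesion_phantom(ps))

  ca <- generate_imaging_cohort(3, seed = 4,
                                base_spec = phantom_spec(grid_shape = c(24, 24, 24),
                                                         spacing = c(2, 2, 2),
                                                         semi_axes = c(12, 10, 9)))
  cb <- generate_imaging_cohort(3, seed = 4,
                                base_spec = phantom_spec(grid_shape = c(24, 24, 24),
                                                         spacing = c(2, 2, 2),
                                                         semi_axes = c(12, 10, 9)))
  expect_identical(ca, cb)
})

test_that("degenerate phantom texture gives a constant-intensity lesion", {
  ph <- generate_lesion_phantom(phantom_spec(
    hypodense_fraction = 0, hyperdense_fraction = 0,
    soft_tissue_hu_std = 0, soft_tissue_hu_mean = 55, seed = 3
  ))
  inside <- ph$volume$intensities[ph$mask == 1]
  expect_equal(unname(range(inside)), c(55, 55), tolerance = 1e-10)
  expect_true(all(ph$volume$intensities[ph$mask == 0] == -90))
})

test_that("phantom mask volume matches the analytic ellipsoid volume", {
  ph <- generate_lesion_phantom(phantom_spec(
    grid_shape = c(25, 25, 25), spacing = c(1, 1, 1),
    semi_axes = c(10, 10, 10), seed = 1
  ))
  expect_equal(sum(ph$mask), 4 / 3 * pi * 1000, tolerance = 0.05)
  shp <- compute_shape_features(ph$mask, c(1, 1, 1))
  expect_equal(unname(shp["shape_Elongation"]), 1, tolerance = 0.02)
})

test_that("inclusion fractions land within 2 percentage points of target", {
  ph <- generate_lesion_phantom(phantom_spec(
    hypodense_fraction = 0.10, hyperdense_fraction = 0.05, seed = 8
  ))
  n <- sum(ph$mask)
  expect_lt(abs(sum(ph$tissue_truth == 1) / n - 0.10), 0.02)
  expect_lt(abs(sum(ph$tissue_truth == 3) / n - 0.05), 0.02)
  expect_error(phantom_spec(hypodense_fraction = 0.6, hyperdense_fraction = 0.5),
               "0.9")
})

test_that("responder shift lowers the least axis length in the label-1 group", {
  base <- phantom_spec(grid_shape = c(28, 28, 28), spacing = c(1.5, 1.5, 1.5),
                       semi_axes = c(14, 12, 10), soft_tissue_hu_std = 10,
                       texture_correlation_length_mm = 0,
                       hypodense_fraction = 0, hyperdense_fraction = 0)
  cohort <- generate_imaging_cohort(
    40, prevalence = 0.5,
    responder_shift = list(semi_axes = c(1, 1, 0.6)),
    seed = 10, base_spec = base
  )
  least <- vapply(cohort, function(pt) {
    unname(compute_shape_features(pt$mask, pt$volume$spacing)["shape_LeastAxisLength"])
  }, numeric(1))
  lab <- vapply(cohort, `[[`, numeric(1), "label")
  expect_gt(sum(lab), 5)
  expect_lt(sum(lab), 35)
  expect_lt(mean(least[lab == 1]), mean(least[lab == 0]))
  # identity shift: no systematic difference
  coh0 <- generate_imaging_cohort(
    30, prevalence = 0.5, responder_shift = list(), seed = 11, base_spec = base
  )
  least0 <- vapply(coh0, function(pt) {
    unname(compute_shape_features(pt$mask, pt$volume$spacing)["shape_LeastAxisLength"])
  }, numeric(1))
  lab0 <- vapply(coh0, `[[`, numeric(1), "label")
  expect_gt(t.test(least0[lab0 == 1], least0[lab0 == 0])$p.value, 0.01)
})

test_that("NIfTI round trip preserves volume, mask, and spacing", {
  ph <- generate_lesion_phantom(phantom_spec(
    grid_shape = c(16, 16, 16), spacing = c(2, 1.5, 1), semi_axes = c(10, 8, 6),
    seed = 2
  ))
  d <- withr::local_tempdir()
  vf <- file.path(d, "vol.nii.gz")
  mf <- file.path(d, "mask.nii.gz")
  write_ct_nifti(ph$volume, vf)
  write_mask_nifti(ph$mask, ph$volume$spacing, mf)
  v2 <- read_ct_nifti(vf)
  m2 <- read_mask_nifti(mf)
  expect_equal(v2$spacing, ph$volume$spacing, tolerance = 1e-5)
  expect_equal(as.vector(v2$intensities), as.vector(ph$volume$intensities),
               tolerance = 1e-5)
  expect_identical(as.vector(m2), as.vector(ph$mask))
})
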