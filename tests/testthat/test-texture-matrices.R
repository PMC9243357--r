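# Run-length, size-zone, dependence, and gray-tone difference features
# against brute-force enumeration oracles.

random_levels <- function(seed, dims = c(4, 4, 4), ng = 3L, drop = 10) {
  set.seed(seed)
  lv <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  lv[sample(prod(dims), drop)] <- NA
  lv
}

test_that("run enumeration matches the brute-force scanner in every direction", {
  lv <- random_levels(13)
  dirs <- crsradiomics:::unique_directions()
  for (r in seq_len(nrow(dirs))) {
    mine <- crsradiomics:::runs_along(lv, dirs[r, ])
    ora <- oracle_runs(lv, dirs[r, ])
    expect_equal(
      sort(paste(mine[, 1], mine[, 2])),
      sort(paste(ora[, 1], ora[, 2]))
    )
  }
})

test_that("constant 2x2x2 lesion yields the hand-counted run set", {
  lv <- array(1L, c(2, 2, 2))
  # along an axis direction: 4 runs of length 2
  ax <- crsradiomics:::runs_along(lv, c(1, 0, 0))
  expect_equal(nrow(ax), 4)
  expect_true(all(ax[, "length"] == 2))
  # along a space diagonal: the single main diagonal run of length 2,
  # and six length-1 runs covering the remaining corners
  dg <- crsradiomics:::runs_along(lv, c(1, 1, 1))
  expect_equal(sort(unname(dg[, "length"])), c(1, 1, 1, 1, 1, 1, 2))
  f <- compute_glrlm_features(lv, 1L)
  expect_equal(unname(f["glrlm_GrayLevelNonUniformityNormalized"]), 1)
})

test_that("size zones match the flood-fill oracle and the constant case", {
  lv <- array(2L, c(3, 3, 3))
  z <- crsradiomics:::zone_list(lv)
  expect_equal(nrow(z), 1)
  expect_equal(unname(z[1, "size"]), 27)

  lv2 <- random_levels(21, dims = c(4, 4, 3), ng = 2L, drop = 8)
  mine <- crsradiomics:::zone_list(lv2)
  ora <- oracle_zones(lv2)
  expect_equal(
    sort(paste(mine[, "level"], mine[, "size"])),
    sort(paste(ora[, 1], ora[, 2]))
  )

  f <- compute_glszm_features(lv, 2L)
  expect_equal(unname(f["glszm_ZonePercentage"]), 1 / 27)
})

test_that("dependence counts match per-voxel enumeration", {
  lv <- random_levels(31, dims = c(4, 3, 4), ng = 3L, drop = 9)
  ora <- oracle_dependence(lv)
  ng <- 3L
  P_oracle <- matrix(0, ng, max(ora[, 2]))
  for (r in seq_len(nrow(ora))) {
    P_oracle[ora[r, 1], ora[r, 2]] <- P_oracle[ora[r, 1], ora[r, 2]] + 1
  }
  f <- compute_gldm_features(lv, ng)
  Nz <- sum(P_oracle)
  J <- t(matrix(seq_len(ncol(P_oracle)), ncol(P_oracle), ng))
  expect_equal(unname(f["gldm_SmallDependenceEmphasis"]),
               sum(P_oracle / J^2) / Nz, tolerance = 1e-10)
  expect_equal(unname(f["gldm_LargeDependenceEmphasis"]),
               sum(P_oracle * J^2) / Nz, tolerance = 1e-10)
  expect_equal(unname(f["gldm_GrayLevelNonUniformity"]),
               sum(rowSums(P_oracle)^2) / Nz, tolerance = 1e-10)
})

test_that("gray-tone difference statistics match neighborhood-mean enumeration", {
  # 3x3x1 two-level checkerboard, hand-checkable neighborhood means
  lv <- array(NA_integer_, c(3, 3, 1))
  lv[, , 1] <- (outer(1:3, 1:3, "+") %% 2L) + 1L
  ng <- 2L
  ora <- oracle_ngtdm_si(lv, ng)
  f <- compute_ngtdm_features(lv, ng)
  p_i <- ora$n_i / ora$nvp
  coarse <- 1 / sum(p_i * ora$s_i)
  pres <- which(p_i > 0)
  ngp <- length(pres)
  contrast <- sum(outer(p_i[pres], p_i[pres]) * outer(pres, pres, "-")^2) /
    (ngp * (ngp - 1)) * sum(ora$s_i) / ora$nvp
  expect_equal(unname(f["ngtdm_Coarseness"]), coarse, tolerance = 1e-10)
  expect_equal(unname(f["ngtdm_Contrast"]), contrast, tolerance = 1e-10)

  # random irregular grid
  lv2 <- random_levels(41, dims = c(4, 4, 2), ng = 3L, drop = 6)
  ora2 <- oracle_ngtdm_si(lv2, 3L)
  f2 <- compute_ngtdm_features(lv2, 3L)
  p2 <- ora2$n_i / ora2$nvp
  expect_equal(unname(f2["ngtdm_Coarseness"]),
               1 / sum(p2 * ora2$s_i), tolerance = 1e-10)
  pres2 <- which(p2 > 0)
  busy_den <- sum(abs(outer(pres2 * p2[pres2], pres2 * p2[pres2], "-")))
  expect_equal(unname(f2["ngtdm_Busyness"]),
               sum(p2 * ora2$s_i) / busy_den, tolerance = 1e-10)
})

test_that("constant lesion degenerates as documented across matrix classes", {
  lv <- array(1L, c(3, 3, 2))
  expect_equal(unname(compute_glszm_features(lv, 1L)["glszm_ZonePercentage"]),
               1 / 18)
  gldm <- compute_gldm_features(lv, 1L)
  expect_equal(unname(gldm["gldm_LowGrayLevelEmphasis"]), 1)
  ngtdm <- compute_ngtdm_features(lv, 1L)
  expect_equal(unname(ngtdm["ngtdm_Contrast"]), 0)
  # single voxel: one run / zone of size 1
  single <- array(NA_integer_, c(3, 3, 3)); single[2, 2, 2] <- 1L
  z <- crsradiomics:::zone_list(single)
  expect_equal(unname(z[1, "size"]), 1)
  r <- crsradiomics:::runs_along(single, c(1, 0, 0))
  expect_equal(unname(r[1, "length"]), 1)
})
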