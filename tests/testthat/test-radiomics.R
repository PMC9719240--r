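test_that("bin width is mean range over bins", {
  expect_equal(determine_bin_width(2.56, 64), 0.04)
  expect_equal(determine_bin_width(c(1, 3), 2), 1)
  expect_equal(determine_bin_width(rep(1.28, 7), 32), 0.04)
  expect_error(determine_bin_width(numeric(0)), "empty")
  expect_error(determine_bin_width(c(1, -1)), "positive")
})

test_that("discretization follows the fixed-bin-width contract", {
  expect_identical(discretize(c(1.40, 1.44, 1.48), 0.04), c(1L, 2L, 3L))
  expect_identical(discretize(rep(2.2, 5), 0.04), rep(1L, 5))
  set.seed(1)
  v <- runif(10000, 1.4, 4.0)
  expect_lte(length(unique(discretize(v, 0.04))), ceiling(2.6 / 0.04) + 1)
  # grid-aligned anchor shifts all levels by a constant
  lv1 <- discretize(c(1.41, 1.47, 1.53), 0.04, "voi_minimum")
  lv2 <- discretize(c(1.41, 1.47, 1.53), 0.04, "grid_aligned")
  expect_true(length(unique(lv2 - lv1)) == 1)
})

test_that("texture matrices match brute-force enumeration on random grids", {
  for (seed in 1:10) {
    g <- random_level_grid(seed)
    tm <- compute_texture_matrices(g$lev, g$mask)
    lv <- tm$level_values
    expect_equal(tm$glcm_angles, oracle_glcm(g$lev, g$mask, lv))
    expect_equal(tm$glrlm_angles, oracle_glrlm(g$lev, g$mask, lv))
    expect_equal(tm$glszm, oracle_glszm(g$lev, g$mask, lv))
    o_ngtdm <- oracle_ngtdm(g$lev, g$mask, lv)
    expect_equal(tm$ngtdm$n, o_ngtdm$n)
    expect_equal(tm$ngtdm$s, o_ngtdm$s)
    expect_equal(tm$gldm, oracle_gldm(g$lev, g$mask, lv))
    expect_equal(sum(tm$glcm), 1, tolerance = 1e-12)
  }
})

test_that("hand-enumerable texture cases come out exactly", {
  # 2x2x1 grid, levels [[1,1],[1,2]]
  lev <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  mask <- array(TRUE, c(2, 2, 1))
  tm <- compute_texture_matrices(lev, mask)
  expect_equal(tm$glcm_angles, oracle_glcm(lev, mask, tm$level_values))
  # constant VOI: merged GLCM is the single cell 1
  lev2 <- array(3L, c(3, 3, 2))
  tm2 <- compute_texture_matrices(lev2, array(TRUE, c(3, 3, 2)))
  expect_identical(dim(tm2$glcm), c(1L, 1L))
  expect_equal(tm2$glcm[1, 1], 1)
  # 1x4x1 run [1,1,2,2] along y: one run of length 2 per level
  lev3 <- array(c(1L, 1L, 2L, 2L), c(1, 4, 1))
  tm3 <- compute_texture_matrices(lev3, array(TRUE, c(1, 4, 1)))
  ydir <- which(apply(fetrad:::conn_offsets(26), 1, identical, c(dx = 0L, dy = 1L, dz = 0L)))
  expect_equal(tm3$glrlm_angles[, , ydir], matrix(c(0, 0, 1, 1), 2, 2))
})

test_that("first-order features match closed forms and degenerate rules", {
  fo <- first_order_features(rep(4.2, 10), rep(1L, 10), c(1, 1, 1))
  expect_equal(unname(fo[c("FO_Mean", "FO_Median", "FO_Minimum", "FO_Maximum")]),
               rep(4.2, 4))
  expect_equal(unname(fo["FO_Variance"]), 0)
  expect_equal(unname(fo["FO_Skewness"]), 0)
  expect_equal(unname(fo["FO_Entropy"]), 0)
  expect_equal(unname(fo["FO_Uniformity"]), 1)
  fo2 <- first_order_features(1:4, discretize(1:4 + 0, 1), c(1, 1, 1))
  expect_equal(unname(fo2["FO_Mean"]), 2.5)
  expect_equal(unname(fo2["FO_Variance"]), 1.25)  # population variance
  set.seed(42)
  x <- rnorm(1000, 2, 0.5)
  fo3 <- first_order_features(x, discretize(x, 0.04), c(1, 1, 1))
  expect_lt(abs(fo3["FO_Skewness"]), 0.15)
  expect_lt(abs(fo3["FO_RootMeanSquared"] - sqrt(4.25)) / sqrt(4.25), 0.02)
})

test_that("shape axes match the analytic solid-ellipsoid covariance", {
  # uniform solid ellipsoid: coordinate covariance eigenvalues a^2/5, b^2/5, c^2/5
  sp <- c(2.035, 2.035, 2.425)
  d <- c(40, 40, 32)
  ax <- c(30, 15, 15)
  ctr <- (d + 1) / 2
  co <- arrayInd(seq_len(prod(d)), d)
  r2 <- ((co[, 1] - ctr[1]) * sp[1] / ax[1])^2 +
    ((co[, 2] - ctr[2]) * sp[2] / ax[2])^2 +
    ((co[, 3] - ctr[3]) * sp[3] / ax[3])^2
  mask <- array(r2 <= 1, d)
  sf <- shape_features(mask, sp)
  expect_lt(abs(sf["SH_MajorAxisLength"] - 4 * ax[1] / sqrt(5)) /
              (4 * ax[1] / sqrt(5)), 0.05)
  expect_lt(abs(sf["SH_Elongation"] - 0.5), 0.05)
  expect_lt(abs(sf["SH_Maximum3DDiameter"] - 2 * ax[1]) / (2 * ax[1]), 0.10)
  # similarity scaling: doubling the spacing doubles lengths, not ratios
  sf2 <- shape_features(mask, 2 * sp)
  expect_equal(unname(sf2["SH_MajorAxisLength"] / sf["SH_MajorAxisLength"]), 2)
  expect_equal(unname(sf2["SH_Elongation"]), unname(sf["SH_Elongation"]))
  expect_true(sf["SH_MajorAxisLength"] >= sf["SH_MinorAxisLength"])
  expect_true(sf["SH_MinorAxisLength"] >= sf["SH_LeastAxisLength"])
  expect_true(sf["SH_Elongation"] >= 0 && sf["SH_Elongation"] <= 1)
})

test_that("single-voxel masks use the documented degenerate conventions", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  sf <- shape_features(m, c(1, 1, 1))
  expect_equal(unname(sf["SH_MajorAxisLength"]), 0)
  expect_equal(unname(sf["SH_Elongation"]), 1)
  expect_equal(unname(sf["SH_VoxelVolume"]), 1)
  img <- pet_volume(array(2, c(5, 5, 5)), c(1, 1, 1))
  fv <- extract_features(img, voi_mask(m, "voi16", 1.6, c(1, 1, 1)))
  expect_length(fv, 107)
  expect_false(any(!is.finite(fv)))
})

test_that("the full feature vector has 107 features in the documented classes", {
  dp <- digital_phantom()
  fv <- extract_features(dp$image, dp$mask, binning_spec(0.04))
  expect_length(fv, 107)
  cls <- attr(fv, "class_of")
  counts <- vapply(names(feature_class_counts()), function(k) sum(cls == k),
                   integer(1))
  expect_identical(counts, feature_class_counts())
  fv32 <- extract_features(dp$image, dp$mask, binning_spec(0.04),
                           classes = c("SH", "FO"))
  expect_length(fv32, 32)
})

test_that("texture features are invariant to intensity shifts under voi_minimum", {
  dp <- digital_phantom()
  b <- binning_spec(0.04, anchor = "voi_minimum")
  f1 <- extract_features(dp$image, dp$mask, b)
  shifted <- pet_volume(dp$image$data + 3.7, dp$image$spacing)
  f2 <- extract_features(shifted, dp$mask, b)
  tex <- names(f1)[attr(f1, "class_of") %in% c("GLCM", "GLRLM", "GLSZM",
                                               "NGTDM", "GLDM")]
  expect_equal(f1[tex], f2[tex], tolerance = 1e-10)
})
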