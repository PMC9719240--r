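test_that("background estimation recovers constant and noisy levels", {
  img <- pet_volume(array(5, c(10, 10, 10)), c(2, 2, 2))
  bg_mask <- array(TRUE, c(10, 10, 10))
  expect_equal(estimate_background(img, background_mask = bg_mask), 5)
  img1 <- pet_volume(array(1, c(10, 10, 10)), c(2, 2, 2))
  expect_equal(estimate_background(img1, background_mask = bg_mask), 1)
  expect_error(estimate_background(img, background_mask = array(FALSE, c(10, 10, 10))),
               "empty background")
  # noisy background, shell mode: recovered within 2% of 1.0 across seeds
  sp <- tiny_scanner(noise = 0.05)
  levels <- vapply(1:100, function(s) {
    ph <- generate_phantom(tumor_spec(c(6, 5, 4), peak_tbr = 2), sp, seed = s)
    estimate_background(ph$volume, "contralateral_shell",
                        center_vox = c(18, 18, 15),
                        shell_inner = 15, shell_outer = 30)
  }, numeric(1))
  expect_true(all(abs(levels - 1) < 0.02))
})

test_that("TBR thresholds give nested VOIs and report empty results", {
  sp <- tiny_scanner()
  ph <- generate_phantom(tumor_spec(c(14, 12, 10), peak_tbr = 2.5,
                                    uptake_profile = "linear"), sp, 1)
  ctr <- round(dim(ph$volume$data) / 2)
  vois <- segment_tbr_set(ph$volume, 1, ctr)
  expect_named(vois, c("voi14", "voi16", "voi18"))
  expect_true(all(vois$voi16$mask[vois$voi18$mask]))
  expect_true(all(vois$voi14$mask[vois$voi16$mask]))
  expect_gt(vois$voi14$n_voxels, vois$voi18$n_voxels)
  flat <- pet_volume(array(1, c(8, 8, 8)), c(2, 2, 2))
  for (th in c(1.4, 1.6, 1.8)) {
    expect_error(segment_tbr(flat, 1, th, c(4, 4, 4)), class = "fetrad_empty_voi")
  }
})

test_that("voi14 voxel count matches the analytic isocontour volume", {
  sp <- scanner_profile("iso", c(1.5, 1.5, 1.5), 0, 0, c(60, 60, 48))
  a <- c(20, 14, 12); peak <- 2.5
  ph <- generate_phantom(tumor_spec(a, peak_tbr = peak, uptake_profile = "linear"),
                         sp, 1)
  v14 <- segment_tbr(ph$volume, 1, 1.4, round(dim(ph$volume$data) / 2))
  r_star <- 1 - (1.4 - 1) / (peak - 1)   # normalized radius of the 1.4 contour
  vol_mm3 <- 4 / 3 * pi * prod(a) * r_star^3
  expect_lt(abs(v14$n_voxels * prod(sp$voxel_spacing) - vol_mm3) / vol_mm3, 0.10)
})

test_that("VOIs are invariant to common rescaling of image and background", {
  sp <- tiny_scanner()
  ph <- generate_phantom(tumor_spec(c(12, 10, 8), peak_tbr = 2.2,
                                    uptake_profile = "linear"), sp, 2)
  ctr <- round(dim(ph$volume$data) / 2)
  m1 <- segment_tbr(ph$volume, 1, 1.6, ctr)
  scaled <- pet_volume(ph$volume$data * 7.3, sp$voxel_spacing)
  m2 <- segment_tbr(scaled, 7.3, 1.6, ctr)
  expect_identical(m1$mask, m2$mask)
})

test_that("PTV cleaning is exact set difference with loud emptiness", {
  m <- array(FALSE, c(10, 10, 5)); m[2:9, 2:9, 2:4] <- TRUE
  ptv <- voi_mask(m, "ptv", NA, c(2, 2, 2))
  expect_identical(clean_ptv(ptv)$mask, ptv$mask)
  excl <- array(FALSE, c(10, 10, 5)); excl[2:6, 2:9, 2:4] <- TRUE
  cleaned <- clean_ptv(ptv, excl)
  expect_identical(cleaned$n_voxels, ptv$n_voxels - sum(ptv$mask & excl))
  expect_error(clean_ptv(ptv, m), class = "fetrad_empty_voi")
  expect_error(clean_ptv(ptv, array(FALSE, c(3, 3, 3))), "grid mismatch")
})

test_that("off-seed points relocate to the nearest component within reach", {
  sp <- tiny_scanner()
  ph <- generate_phantom(tumor_spec(c(10, 8, 8), peak_tbr = 2.5), sp, 1)
  ctr <- round(dim(ph$volume$data) / 2)
  near_edge <- ctr + c(8, 0, 0)   # outside tumor, within 30 mm
  m <- segment_tbr(ph$volume, 1, 1.6, near_edge)
  expect_gt(m$n_voxels, 0)
  expect_error(segment_tbr(ph$volume, 1, 1.6, c(1, 1, 1), search_radius_mm = 5),
               class = "fetrad_empty_voi")
})
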