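test_that("noiseless flat phantom is exactly peak inside and 1 outside", {
  sp <- tiny_scanner()
  ts <- tumor_spec(c(14, 10, 8), peak_tbr = 2.5)
  ph <- generate_phantom(ts, sp, seed = 1)
  expect_true(all(ph$volume$data[ph$tumor_mask] == 2.5))
  expect_true(all(ph$volume$data[!ph$tumor_mask] == 1.0))
})

test_that("background mean is exactly 1 before filtering when noise_cv = 0", {
  ph <- generate_phantom(tumor_spec(c(10, 10, 10), texture_amplitude = 0.2),
                         tiny_scanner(), seed = 3)
  expect_identical(mean(ph$volume$data[!ph$tumor_mask]), 1)
})

test_that("spherical tumor has truth elongation 1 and major axis 2a", {
  ph <- generate_phantom(tumor_spec(c(20, 20, 20)), tiny_scanner(grid = c(40, 40, 36)),
                         seed = 1)
  expect_equal(unname(ph$truth["elongation"]), 1.0)
  expect_equal(unname(ph$truth["major_axis_mm"]), 40)
})

test_that("invalid tumors are rejected", {
  expect_error(tumor_spec(c(10, 12, 8)), "descending")
  expect_error(tumor_spec(c(10, 8, 6), peak_tbr = 0.9), "peak_tbr")
  # tumor larger than the grid
  expect_error(generate_phantom(tumor_spec(c(60, 40, 40)), tiny_scanner(), 1),
               "exceeds grid")
})

test_that("exponential survival link has the right mean and PH scaling", {
  link <- survival_link(baseline_hazard = 1 / 500, coefficients = numeric(0),
                        centers = numeric(0))
  times <- vapply(1:10000, function(i)
    simulate_survival(c(major_axis_mm = 0), link, seed = i)$time_days,
    numeric(1))
  expect_lt(abs(mean(times) - 500) / 500, 0.03)  # exponential mean = 1/lambda
  # adding log(2) to the log-hazard halves median survival
  link2 <- survival_link(baseline_hazard = 1 / 500,
                         coefficients = c(z = log(2)), centers = c(z = 0))
  t2 <- vapply(1:10000, function(i)
    simulate_survival(c(z = 1), link2, seed = i)$time_days, numeric(1))
  expect_lt(abs(median(t2) / median(times) - 0.5), 0.03)
})

test_that("missing covariates fail loudly and labels follow the 1-year rule", {
  link <- survival_link()
  expect_error(simulate_survival(c(not_it = 1), link), "missing from truth")
  sv <- simulate_survival(c(major_axis_mm = 42), link, seed = 5)
  expect_identical(sv$label_1yr, as.integer(sv$time_days >= 365))
  expect_identical(sv$event, 1L)
})

test_that("positive coefficient on major axis induces negative time association", {
  link <- survival_link(coefficients = c(major_axis_mm = 0.05),
                        centers = c(major_axis_mm = 42))
  set.seed(11)
  axis <- runif(500, 24, 60)
  times <- vapply(seq_along(axis), function(i)
    simulate_survival(c(major_axis_mm = axis[i]), link, seed = 1000 + i)$time_days,
    numeric(1))
  expect_lt(cor(axis, times, method = "kendall"), 0)
  # planted-effect monotonicity: top tertile of axis survives less on average
  ter <- cut(axis, quantile(axis, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE,
             labels = FALSE)
  expect_lt(mean(times[ter == 3]), mean(times[ter == 1]))
})

test_that("cohorts are bit-identical under identical seeds and PTV contains voi16", {
  cs <- cohort_spec(4, tiny_scanner(noise = 0.05),
                    tumor_ranges = list(a = c(8, 14), center_jitter = 2),
                    ptv_margin = 12, seed = 9)
  link <- survival_link(seed = 2)
  c1 <- generate_cohort(cs, link)
  c2 <- generate_cohort(cs, link)
  expect_identical(c1$survival, c2$survival)
  for (i in seq_along(c1$subjects)) {
    expect_identical(c1$subjects[[i]]$volume$data, c2$subjects[[i]]$volume$data)
  }
  for (s in c1$subjects) {
    bg <- estimate_background(s$volume, background_mask = s$background_mask)
    seedpt <- round(colMeans(arrayInd(which(s$tumor_mask), dim(s$tumor_mask))))
    v16 <- segment_tbr(s$volume, bg, 1.6, seedpt)
    expect_true(all(s$ptv$mask[v16$mask]))      # dilation superset
    expect_gt(s$ptv$n_voxels, v16$n_voxels)
  }
})

test_that("the two-profile study cohort honours the 25/12 design at any size", {
  co <- generate_study_cohort(n_train = 3, n_test = 2, seed = 4,
                              train_profile = tiny_scanner(),
                              test_profile = scanner_profile(
                                "tiny3d", c(1.1, 1.1, 2), 5, 0.05, c(64, 64, 36)),
                              tumor_ranges = list(a = c(8, 12), center_jitter = 2),
                              ptv_margin = 10)
  expect_identical(sum(co$survival$scanner == "tiny"), 3L)
  expect_identical(sum(co$survival$scanner == "tiny3d"), 2L)
  expect_identical(nrow(co$survival), 5L)
  expect_identical(length(co$subjects), 5L)
})
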