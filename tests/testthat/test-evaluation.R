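# Small two-profile cohort reused across evaluation tests (coarse grids,
# shape + first-order features only, minimal search budget).
eval_cohort <- function(seed = 13) {
  generate_study_cohort(
    n_train = 8, n_test = 6, seed = seed,
    link = survival_link(coefficients = c(major_axis_mm = 0.08),
                         centers = c(major_axis_mm = 24)),
    train_profile = scanner_profile("osem2d", c(2.035, 2.035, 2.425), 0, 0.08,
                                    c(40, 40, 32)),
    test_profile = scanner_profile("osem3d", c(1.5, 1.5, 2.027), 5, 0.10,
                                   c(56, 56, 36)),
    tumor_ranges = list(a = c(8, 16), center_jitter = 2), ptv_margin = 10)
}

eval_config <- function() {
  list(classes = c("FO", "SH"), n_bins = 64,
       rf_spec = rf_search_spec(n_settings = 2, cv_folds = 2, seed = 5),
       seed = 11)
}

test_that("the independent scenario fills the full 32-cell grid", {
  co <- eval_cohort()
  suppressWarnings(expect_warning(fetrad:::prepare_subject_data(co), "empty VOI"))
  rep <- suppressWarnings(run_scenario(scenario_spec("independent"), co, eval_config()))
  expect_identical(nrow(rep), 32L)   # 4 VOIs x 4 variants x 2 tasks
  expect_setequal(unique(rep$voi), c("voi14", "voi16", "voi18", "ptv"))
  expect_setequal(unique(rep$variant), c("Top", "PC", "PC(SH-FO)", "SH-FO"))
  expect_setequal(unique(rep$metric), c("AUC", "C-index"))
  # highlight rule: strictly above 0.65
  ok <- !is.na(rep$value)
  expect_identical(rep$highlight[ok], rep$value[ok] > 0.65)
  expect_false(any(rep$highlight[!ok]))
  # every cell present or explicitly annotated
  expect_true(all(ok | nzchar(rep$note)))
})

test_that("combined CV partitions every subject into exactly one test fold", {
  co <- eval_cohort()
  cfg <- eval_config()
  cfg$vois <- "ptv"; cfg$variants <- "SH-FO"; cfg$tasks <- "regress_days"
  rep <- suppressWarnings(run_scenario(scenario_spec("combined_cv", folds = 5, seed = 2), co, cfg))
  fold <- attr(rep, "fold_assignment")
  expect_identical(length(fold), 14L)
  expect_identical(sort(unique(fold)), 1:5)
  expect_identical(sum(tabulate(fold)), 14L)
})

test_that("univariate screening is empty on empty input and null-calibrated", {
  empty <- univariate_screen_report(list(), data.frame())
  expect_identical(nrow(empty), 0L)
  # null features: about alpha * m significant per replicate
  set.seed(41)
  counts <- vapply(1:30, function(r) {
    n <- 40
    t <- rexp(n, 1 / 400)
    m <- matrix(rnorm(n * 50), n, dimnames = list(NULL, paste0("f", 1:50)))
    rownames(m) <- sprintf("s%02d", 1:n)
    ds <- list(voi14 = list(matrix = m))
    sv <- data.frame(subject_id = rownames(m), time_days = t, event = 1)
    sum(univariate_screen_report(ds, sv)$significant)
  }, numeric(1))
  expect_gt(mean(counts), 0.8)   # around 2.5 expected under the null
  expect_lt(mean(counts), 5)
})

test_that("cell failures are recorded, not fatal", {
  co <- eval_cohort()
  cfg <- eval_config()
  cfg$vois <- "ptv"; cfg$variants <- "SH-FO"
  # single-class labels make classification cells fail gracefully
  co$survival$label_1yr <- 1L
  rep <- suppressWarnings(run_scenario(scenario_spec("independent"), co, cfg))
  cls <- rep[rep$task == "classify_1yr", ]
  expect_true(all(is.na(cls$value)))
  expect_true(all(nzchar(cls$note)))
  reg <- rep[rep$task == "regress_days", ]
  expect_true(all(is.finite(reg$value)))
})
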