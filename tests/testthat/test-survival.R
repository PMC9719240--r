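test_that("AUC is the pair-ordering probability, checked against pROC", {
  set.seed(21)
  y <- rbinom(500, 1, 0.4)
  s <- rnorm(500)
  expect_lt(abs(auc_score(y, s) - 0.5), 0.05)       # chance level
  # monotone invariance
  expect_equal(auc_score(y, s), auc_score(y, exp(3 * s)))
  skip_if_not_installed("pROC")
  s2 <- rnorm(500) + y
  expect_equal(auc_score(y, s2),
               as.numeric(pROC::auc(pROC::roc(y, s2, quiet = TRUE,
                                              direction = "<"))))
  expect_true(is.na(auc_score(rep(1, 5), rnorm(5))))
})

test_that("C-index agrees with the survival package and is antisymmetric", {
  set.seed(22)
  n <- 120
  t <- rexp(n, 1 / 400)
  e <- rep(1, n)
  pred <- t + rnorm(n, sd = 200)
  ci <- concordance_index(t, e, pred)
  ref <- survival::concordance(survival::Surv(t, e) ~ pred)$concordance
  expect_equal(ci, unname(ref), tolerance = 1e-12)
  expect_equal(concordance_index(t, e, t), 1)          # perfect ordering
  expect_equal(concordance_index(t, e, -pred), 1 - ci) # antisymmetry
  # random predictor near 0.5
  expect_lt(abs(concordance_index(t, e, rnorm(n)) - 0.5), 0.12)
})

test_that("univariate Cox recovers a planted hazard ratio of 2", {
  set.seed(23)
  n <- 1000
  x <- rnorm(n)
  t <- rexp(n, rate = (1 / 500) * 2^x)
  fit <- fit_univariate_cox(x, t, rep(1, n))
  expect_true(fit$converged)
  expect_gt(fit$hazard_ratio, 1.8)
  expect_lt(fit$hazard_ratio, 2.2)
  expect_lt(fit$p_value, 1e-6)
  expect_true(fit$significant)
})

test_that("degenerate Cox inputs are flagged, not propagated", {
  set.seed(24)
  t <- rexp(50, 1 / 300)
  f <- fit_univariate_cox(rep(2, 50), t, rep(1, 50))
  expect_equal(f$hazard_ratio, 1)
  expect_false(f$significant)
  expect_false(f$converged)
  expect_error(fit_univariate_cox(1:5, rexp(5), rep(1, 5)), "n >= 10")
})

test_that("median-split stratification and the log-rank test behave", {
  # identical survival in both groups: statistic 0, p = 1
  tt <- rep(c(100, 200, 300), 2)
  grp_feature <- rep(c(0, 1), each = 3)
  km0 <- km_median_split(grp_feature, tt, rep(1, 6))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p_value, 1)
  # hazard ratio 2 between arms: overwhelming evidence at n = 500/arm
  set.seed(25)
  t1 <- rexp(500, 1 / 600); t2 <- rexp(500, 2 / 600)
  kmp <- km_median_split(rep(c(0, 1), each = 500), c(t1, t2), rep(1, 1000))
  expect_lt(kmp$p_value, 0.001)
  expect_error(km_median_split(rep(1, 10), rexp(10), rep(1, 10)), "constant")
})

test_that("coarse-to-fine search is deterministic and never loses ground", {
  set.seed(26)
  n <- 60
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(x[, 1] + rnorm(n, sd = 0.8) > 0)
  spec <- rf_search_spec("classify_1yr", n_settings = 4, cv_folds = 3, seed = 31)
  r1 <- coarse_to_fine_search(spec, x, y)
  r2 <- coarse_to_fine_search(spec, x, y)
  expect_identical(r1$trace, r2$trace)       # reproducible run-to-run
  expect_identical(r1$best, r2$best)
  for (sd_ in 1:5) {
    sp <- rf_search_spec("classify_1yr", n_settings = 3, cv_folds = 3, seed = sd_)
    rr <- coarse_to_fine_search(sp, x, y)
    s1 <- max(rr$trace$score[rr$trace$stage == 1], na.rm = TRUE)
    s2 <- max(rr$trace$score[rr$trace$stage == 2], na.rm = TRUE)
    expect_gte(s2, s1)                       # refinement cannot regress
  }
  expect_error(coarse_to_fine_search(spec, x, rep(1L, n)), "degenerate")
})

test_that("a singleton grid survives both stages unchanged", {
  set.seed(27)
  n <- 40
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rexp(n, 1 / 300)
  spec <- rf_search_spec("regress_days", n_trees_range = c(100, 100),
                         min_node_range = c(5, 5), mtry_frac_range = c(1, 1),
                         refine_factor = 1.0001, n_settings = 2, cv_folds = 2,
                         seed = 5)
  r <- coarse_to_fine_search(spec, x, y)
  expect_identical(unname(unlist(r$best)), c(100L, 5L, 3L))
})

test_that("train_and_predict scores chance data at chance and signal above it", {
  set.seed(28)
  n_tr <- 80; n_te <- 60
  x_tr <- matrix(rnorm(n_tr * 4), n_tr, dimnames = list(NULL, paste0("f", 1:4)))
  x_te <- matrix(rnorm(n_te * 4), n_te, dimnames = list(NULL, paste0("f", 1:4)))
  mk_surv <- function(x) {
    t <- rexp(nrow(x), (1 / 450) * exp(0.8 * x[, 1]))
    data.frame(subject_id = seq_len(nrow(x)), time_days = t, event = 1,
               label_1yr = as.integer(t >= 365))
  }
  sv_tr <- mk_surv(x_tr); sv_te <- mk_surv(x_te)
  spec <- rf_search_spec(n_settings = 4, cv_folds = 3, seed = 17)
  res <- train_and_predict("classify_1yr", x_tr, x_te, sv_tr, sv_te, spec)
  expect_gt(res$metric[["auc"]], 0.6)
  resr <- train_and_predict("regress_days", x_tr, x_te, sv_tr, sv_te, spec)
  expect_gt(resr$metric[["cindex"]], 0.55)
  # labels independent of features: AUC near 0.5
  sv_te_null <- sv_te
  set.seed(29)
  sv_te_null$label_1yr <- sample(sv_te$label_1yr)
  res0 <- train_and_predict("classify_1yr", x_tr, x_te, sv_tr, sv_te_null, spec)
  expect_lt(abs(res0$metric[["auc"]] - 0.5), 0.2)
})

test_that("test-set survival never influences the fitted model", {
  set.seed(30)
  x_tr <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("f", 1:3)))
  x_te <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, paste0("f", 1:3)))
  sv <- function(n, seed) {
    set.seed(seed)
    t <- rexp(n, 1 / 400)
    data.frame(time_days = t, event = 1, label_1yr = as.integer(t >= 365))
  }
  spec <- rf_search_spec(n_settings = 2, cv_folds = 2, seed = 3)
  a <- train_and_predict("classify_1yr", x_tr, x_te, sv(40, 1), sv(20, 2), spec)
  b <- train_and_predict("classify_1yr", x_tr, x_te, sv(40, 1), sv(20, 999), spec)
  expect_identical(a$chosen, b$chosen)
  expect_identical(a$predictions, b$predictions)  # model unchanged, data-leak free
})
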