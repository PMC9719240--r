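make_table <- function(m, ids = sprintf("s%02d", seq_len(nrow(m)))) {
  data.frame(subject_id = ids, m)
}

test_that("standardization uses population moments and flags constants", {
  tab <- make_table(data.frame(a = c(1, 2, 3), b = c(2, 2, 2)))
  expect_warning(std <- fit_standardizer(tab), "zero-variance")
  z <- apply_standardizer(std, tab)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  # affine contract: a shifted test cohort keeps the shift in standard units
  test <- make_table(data.frame(a = c(1, 2, 3) + 2, b = c(2, 2, 2)))
  zt <- apply_standardizer(std, test)
  expect_equal(zt[, "a"] - z[, "a"], rep(2 / std$scale["a"], 3),
               ignore_attr = TRUE)
})

test_that("PCA by SVD retains components to the variance target", {
  # rank-1: one varying feature
  m <- cbind(a = c(1, 2, 3, 4), b = rep(1, 4), c = rep(2, 4))
  p <- fit_pca(m, 0.95)
  expect_identical(p$n_retained, 1L)
  expect_equal(p$explained_variance_ratio[1], 1)
  # two orthogonal equal-variance signals split 50/50
  m2 <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  p2 <- fit_pca(m2, 0.95)
  expect_equal(unname(p2$explained_variance_ratio), c(0.5, 0.5))
  expect_identical(p2$n_retained, 2L)
  expect_true(all(diff(p2$explained_variance_ratio) <= 1e-12))
})

test_that("PCA scores reproduce explained variance and reconstruct the data", {
  set.seed(3)
  m <- matrix(rnorm(25 * 8), 25, 8)
  colnames(m) <- letters[1:8]
  p <- fit_pca(m, 1)
  s <- pca_scores(p, m, n_components = length(p$explained_variance))
  # population variance of each score equals the explained variance
  v <- apply(s, 2, function(x) mean((x - mean(x))^2))
  expect_equal(unname(v), p$explained_variance, tolerance = 1e-10)
  # orthogonal round trip
  rec <- s %*% t(p$loadings) + matrix(p$center, 25, 8, byrow = TRUE)
  expect_equal(rec, m, tolerance = 1e-8, ignore_attr = TRUE)
  # scores of retained components are orthogonal on the training data
  s2 <- pca_scores(p, m)
  g <- crossprod(scale(s2, scale = FALSE))
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("Top selection keeps the strongest loadings with union semantics", {
  set.seed(7)
  n <- 30
  a <- rnorm(n, sd = 10)           # dominant feature
  m <- cbind(A = a, B = a * 0.5 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 20, sd = 0.05), n,
                    dimnames = list(NULL, paste0("f", 1:20))))
  p <- fit_pca(m, 0.95)
  top <- build_top(p, m, per_component = 10)
  expect_true("A" %in% top$selected)
  expect_lte(ncol(top$matrix), 10 * p$n_retained)
  expect_identical(colnames(top$matrix), top$selected)   # deduplicated union
  # single component keeps exactly 10
  p1 <- fit_pca(cbind(A = a, B = 2 * a, C = -a,
                      matrix(rnorm(n * 9, sd = 1e-6), n,
                             dimnames = list(NULL, paste0("g", 1:9)))), 0.9)
  expect_identical(p1$n_retained, 1L)
  expect_identical(ncol(build_top(p1, cbind(A = a, B = 2 * a, C = -a,
                                            matrix(rnorm(n * 9, sd = 1e-6), n,
                                                   dimnames = list(NULL, paste0("g", 1:9)))),
                                  10)$matrix), 10L)
})

test_that("SH-FO filtering demands complete class coverage and yields 32 columns", {
  dp <- digital_phantom()
  fv <- extract_features(dp$image, dp$mask, binning_spec(0.04))
  cls <- attr(fv, "class_of")
  m <- matrix(rep(as.numeric(fv), each = 5) + rnorm(5 * 107, sd = 0.01), 5,
              dimnames = list(NULL, names(fv)))
  shfo <- build_shfo(m, cls)
  expect_identical(ncol(shfo$matrix), 32L)
  fo_only <- m[, cls[colnames(m)] == "FO"]
  expect_error(build_shfo(fo_only, cls), "class coverage")
})

test_that("PC(SH-FO) on rank-2 data retains two components", {
  set.seed(11)
  u <- rnorm(20); v <- rnorm(20)
  m <- cbind(outer(u, c(1, 2, 0.5)), outer(v, c(1, -1)))
  colnames(m) <- paste0("x", 1:5)
  p <- fit_pca(m, 0.95)
  expect_identical(p$n_retained, 2L)
})

test_that("fitted models never see the test subjects", {
  set.seed(5)
  dpcls <- rep(c("FO", "SH"), times = c(3, 3))
  names(dpcls) <- paste0("x", 1:6)
  tr <- make_table(matrix(rnorm(60), 10, dimnames = list(NULL, paste0("x", 1:6))))
  te1 <- make_table(matrix(rnorm(30), 5, dimnames = list(NULL, paste0("x", 1:6))),
                    sprintf("t%02d", 1:5))
  te2 <- make_table(matrix(rnorm(30, 50), 5, dimnames = list(NULL, paste0("x", 1:6))),
                    sprintf("t%02d", 1:5))
  d1 <- build_dataset_variants(tr, dpcls, te1)
  d2 <- build_dataset_variants(tr, dpcls, te2)
  expect_identical(d1$standardizer, d2$standardizer)
  expect_identical(d1$pca$loadings, d2$pca$loadings)
  expect_identical(d1$train$Top$selected, d2$train$Top$selected)
  expect_identical(d1$train$PC$matrix, d2$train$PC$matrix)
})

test_that("selection frequency counts VOIs in which a feature enters Top", {
  sel1 <- c(A = TRUE, B = FALSE, C = TRUE)
  sel2 <- c(A = TRUE, B = TRUE, C = FALSE)
  tops <- list(voi14 = list(selection = sel1), voi16 = list(selection = sel2))
  cls <- c(A = "SH", B = "FO", C = "GLCM")
  fr <- selection_frequency(tops, cls)
  expect_equal(fr$frequency[fr$feature == "A"], 1)
  expect_equal(fr$frequency[fr$feature == "B"], 0.5)
  expect_equal(fr$frequency[fr$feature == "C"], 0.5)
})
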