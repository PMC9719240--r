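# Standardization, PCA by SVD, and the four dataset variants
# (Top / PC / SH-FO / PC(SH-FO)) fed to the survival models.

feature_matrix <- function(tab) {
  stopifnot(is.data.frame(tab), "subject_id" %in% colnames(tab))
  m <- as.matrix(tab[, setdiff(colnames(tab), "subject_id"), drop = FALSE])
  rownames(m) <- tab$subject_id
  m
}

#' Fit a feature standardizer on training subjects
#'
#' Learns per-feature mean and (population) standard deviation so that the
#' transformed training features have zero mean and unit variance. Test
#' subjects are transformed with the frozen training statistics.
#' Zero-variance features are mapped to 0 with a warning.
#'
#' @param train feature table (data.frame with `subject_id` column) or
#'   numeric matrix.
#' @return An object of class `standardizer` with `center`, `scale` and
#'   `degenerate` (logical per feature).
#' @export
fit_standardizer <- function(train) {
  m <- if (is.data.frame(train)) feature_matrix(train) else as.matrix(train)
  if (nrow(m) < 2) stop("fit_standardizer: need at least 2 training subjects")
  ctr <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2, ctr)^2))  # population sd
  degen <- sds == 0 | !is.finite(sds)
  if (any(degen)) {
    warning(sprintf("%d zero-variance feature(s) mapped to 0: %s",
                    sum(degen), paste(utils::head(colnames(m)[degen], 5),
                                      collapse = ", ")))
    sds[degen] <- 1
  }
  structure(list(center = ctr, scale = sds, degenerate = degen),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer`.
#' @param tab feature table or matrix with the same feature columns.
#' @return Numeric matrix of standardized features (subjects x features).
#' @export
apply_standardizer <- function(std, tab) {
  m <- if (is.data.frame(tab)) feature_matrix(tab) else as.matrix(tab)
  if (!identical(colnames(m), names(std$center))) {
    m <- m[, names(std$center), drop = FALSE]  # errors if features missing
  }
  z <- sweep(sweep(m, 2, std$center), 2, std$scale, "/")
  z[, std$degenerate] <- 0
  z
}

#' Principal component analysis by singular value decomposition
#'
#' Components come from the SVD of the (column-centred) standardized feature
#' matrix. Explained-variance ratios are the normalized squared singular
#' values; the number of retained components is the smallest k whose
#' cumulative ratio reaches `variance_target`. Per-component variances use
#' the population convention (divide by n).
#'
#' @param standardized numeric matrix (subjects x features), already
#'   standardized.
#' @param variance_target fraction of total variance to retain, in (0, 1];
#'   the conventional band is 0.90-0.95 (default 0.95).
#' @return An object of class `pca_model`: `loadings` (features x
#'   components), `explained_variance`, `explained_variance_ratio`,
#'   `n_retained`, `center`, `feature_names`.
#' @export
fit_pca <- function(standardized, variance_target = 0.95) {
  m <- as.matrix(standardized)
  if (nrow(m) < 2) stop("fit_pca: need at least 2 subjects")
  if (!(variance_target > 0 && variance_target <= 1)) {
    stop("fit_pca: variance_target must be in (0, 1]")
  }
  ctr <- colMeans(m)
  x <- sweep(m, 2, ctr)
  sv <- svd(x)
  ev <- sv$d^2 / nrow(m)           # population per-component variance
  keep <- ev > max(ev) * 1e-12     # drop numerically null components
  ev <- ev[keep]
  ratio <- ev / sum(ev)
  cum <- cumsum(ratio)
  n_ret <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(n_ret)) n_ret <- length(ev)
  structure(list(loadings = sv$v[, keep, drop = FALSE],
                 explained_variance = ev,
                 explained_variance_ratio = ratio,
                 n_retained = as.integer(n_ret),
                 variance_target = variance_target,
                 center = ctr, feature_names = colnames(m)),
            class = "pca_model")
}

#' Project standardized data on a fitted PCA model
#'
#' @param pca a `pca_model`.
#' @param standardized matrix with the model's feature columns.
#' @param n_components number of leading components (default the model's
#'   `n_retained`).
#' @return Score matrix (subjects x components), columns `PC1`, `PC2`, ...
#' @export
pca_scores <- function(pca, standardized, n_components = pca$n_retained) {
  m <- as.matrix(standardized)
  if (!is.null(colnames(m)) && !is.null(pca$feature_names)) {
    if (!all(pca$feature_names %in% colnames(m))) {
      stop("pca_scores: feature names do not match the fitted model")
    }
    m <- m[, pca$feature_names, drop = FALSE]
  }
  s <- sweep(m, 2, pca$center) %*% pca$loadings[, seq_len(n_components), drop = FALSE]
  colnames(s) <- paste0("PC", seq_len(n_components))
  s
}

#' PCA-loading feature selection (the Top dataset)
#'
#' For each retained component, the `per_component` features with the
#' largest absolute loading are selected; the dataset columns are the
#' union of the selections (each feature kept once, at its standardized
#' values). Ties at the cutoff are broken by feature-name order. The
#' per-feature selection indicator is exposed for selection-frequency
#' summaries across VOIs.
#'
#' @param pca a `pca_model`.
#' @param standardized standardized matrix the variant should be built from.
#' @param per_component features retained per component (default 10).
#' @return A `dataset_variant` list: `name`, `matrix`, `column_names`,
#'   `selected` (character vector), `selection` (logical per feature).
#' @export
build_top <- function(pca, standardized, per_component = 10) {
  sel <- character(0)
  feats <- pca$feature_names
  for (k in seq_len(pca$n_retained)) {
    ld <- abs(pca$loadings[, k])
    ord <- order(-ld, feats)     # ties broken by fixed feature-name order
    sel <- c(sel, feats[ord[seq_len(min(per_component, length(feats)))]])
  }
  sel <- unique(sel)
  m <- as.matrix(standardized)[, sel, drop = FALSE]
  selection <- stats::setNames(feats %in% sel, feats)
  structure(list(name = "Top", matrix = m, column_names = sel,
                 selected = sel, selection = selection, pca = pca),
            class = "dataset_variant")
}

#' Principal-component score datasets (PC and PC(SH-FO))
#'
#' @param pca a `pca_model` fitted on the full 107-feature set (PC) or on
#'   the 32 shape + first-order features (PC(SH-FO)).
#' @param standardized standardized matrix to project.
#' @param name variant label.
#' @return A `dataset_variant` whose matrix holds the retained component
#'   scores.
#' @export
build_pc <- function(pca, standardized, name = "PC") {
  s <- pca_scores(pca, standardized)
  structure(list(name = name, matrix = s, column_names = colnames(s), pca = pca),
            class = "dataset_variant")
}

#' Shape + first-order dataset (SH-FO)
#'
#' @param standardized standardized matrix with named columns.
#' @param class_of named character vector mapping feature name to class.
#' @return A `dataset_variant` with the 14 + 18 = 32 class-filtered columns.
#' @export
build_shfo <- function(standardized, class_of) {
  m <- as.matrix(standardized)
  if (is.null(class_of) || !all(colnames(m) %in% names(class_of))) {
    stop("build_shfo: class annotations missing for some features")
  }
  keep <- colnames(m)[class_of[colnames(m)] %in% c("SH", "FO")]
  if (!all(c("SH", "FO") %in% class_of[keep])) {
    stop("build_shfo: incomplete class coverage (need both SH and FO features)")
  }
  structure(list(name = "SH-FO", matrix = m[, keep, drop = FALSE],
                 column_names = keep),
            class = "dataset_variant")
}

#' Build all four dataset variants from a training feature table
#'
#' Fits the standardizer and both PCA models on the training subjects only,
#' then materializes Top, PC, SH-FO and PC(SH-FO) for the training set and
#' (with the frozen models) for an optional test set.
#'
#' @param train feature table (data.frame) of training subjects.
#' @param class_of feature-class map (attribute `class_of` of the table is
#'   used when `NULL`).
#' @param test optional feature table of test subjects.
#' @param variance_target PCA variance target.
#' @param per_component Top-dataset features per component.
#' @return List with `train` and (if given) `test`, each a named list of
#'   `dataset_variant`s, plus the fitted `standardizer` and PCA models.
#' @export
build_dataset_variants <- function(train, class_of = NULL, test = NULL,
                                   variance_target = 0.95, per_component = 10) {
  if (is.null(class_of)) class_of <- attr(train, "class_of")
  std <- fit_standardizer(train)
  ztr <- apply_standardizer(std, train)
  pca_all <- fit_pca(ztr, variance_target)
  shfo_tr <- build_shfo(ztr, class_of)
  pca_shfo <- fit_pca(shfo_tr$matrix, variance_target)
  mk <- function(z) {
    shfo <- build_shfo(z, class_of)
    list(Top = build_top(pca_all, z, per_component),
         PC = build_pc(pca_all, z, "PC"),
         `SH-FO` = shfo,
         `PC(SH-FO)` = build_pc(pca_shfo, shfo$matrix, "PC(SH-FO)"))
  }
  out <- list(train = mk(ztr), standardizer = std,
              pca = pca_all, pca_shfo = pca_shfo)
  if (!is.null(test)) out$test <- mk(apply_standardizer(std, test))
  out
}

#' Selection frequency of features across VOIs
#'
#' The fraction of VOIs in which each feature entered the Top dataset —
#' the statistic behind frequency circle plots summarizing which feature
#' classes dominate PCA-based selection.
#'
#' @param top_variants named list (by VOI) of Top `dataset_variant`s.
#' @param class_of feature-class map.
#' @return data.frame with `feature`, `class`, `frequency` (in [0, 1]),
#'   sorted by decreasing frequency.
#' @export
selection_frequency <- function(top_variants, class_of) {
  feats <- names(top_variants[[1]]$selection)
  cnt <- Reduce(`+`, lapply(top_variants, function(v) as.integer(v$selection[feats])))
  out <- data.frame(feature = feats,
                    class = unname(class_of[feats]),
                    frequency = cnt / length(top_variants))
  out[order(-out$frequency, out$feature), , drop = FALSE]
}
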