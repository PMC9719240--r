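# Orchestration of the testing scenarios: independent cross-scanner testing
# and k-fold cross-validation on the combined cohort, over
# VOIs x dataset variants x tasks, with strict train-only fitting of the
# bin width, standardizer and PCA inside every training portion.

#' Scenario specification
#'
#' @param name `"independent"` (train on one scanner profile, test on the
#'   other) or `"combined_cv"` (k-fold cross-validation over the pooled
#'   cohort).
#' @param train_scanner,test_scanner scanner labels for the independent
#'   scenario (must differ).
#' @param folds fold count for `combined_cv` (default 5).
#' @param seed integer seed (fold assignment).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("independent", "combined_cv"),
                          train_scanner = "osem2d", test_scanner = "osem3d",
                          folds = 5, seed = 1L) {
  name <- match.arg(name)
  if (name == "independent" && identical(train_scanner, test_scanner)) {
    stop("scenario_spec: independent scenario needs disjoint scanner labels")
  }
  structure(list(name = name, train_scanner = train_scanner,
                 test_scanner = test_scanner, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Segment every subject once (background estimate, TBR map, the three
# threshold VOIs and the PTV) so repeated extractions with different bin
# widths reuse the geometry.
prepare_subject_data <- function(cohort, thresholds = c(1.4, 1.6, 1.8)) {
  lapply(cohort$subjects, function(s) {
    bg <- estimate_background(s$volume, "provided_mask",
                              background_mask = s$background_mask)
    tbr <- pet_volume(s$volume$data / bg, s$volume$spacing, s$volume$profile)
    seed_point <- round(colMeans(arrayInd(which(s$tumor_mask), dim(s$tumor_mask))))
    masks <- lapply(thresholds, function(th) {
      tryCatch(segment_tbr(tbr, 1, th, seed_point),
               fetrad_empty_voi = function(e) {
                 warning(sprintf("%s: empty VOI at TBR %.2f", s$id, th),
                         call. = FALSE)
                 NULL
               })
    })
    names(masks) <- sprintf("voi%02d", round(thresholds * 10))
    masks$ptv <- s$ptv
    v14 <- if (is.null(masks[[1]])) NULL else tbr$data[masks[[1]]$mask]
    list(id = s$id, scanner = s$volume$profile, tbr = tbr, masks = masks,
         voi14_range = if (is.null(v14)) NA_real_ else diff(range(v14)))
  })
}

# Subjects whose VOI is empty at a given threshold are omitted from that
# VOI's feature table (downstream cells subset to the available subjects).
extract_prepared <- function(prep, binning, classes, vois) {
  out <- list()
  for (v in vois) {
    rows <- lapply(prep, function(s) {
      if (is.null(s$masks[[v]])) return(NULL)
      fv <- extract_features(s$tbr, s$masks[[v]], binning, classes)
      row <- data.frame(subject_id = s$id, t(as.numeric(fv)))
      colnames(row) <- c("subject_id", names(fv))
      attr(row, "class_of") <- attr(fv, "class_of")
      row
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) stop(sprintf("no subject has a nonempty %s", v))
    tab <- do.call(rbind, rows)
    attr(tab, "class_of") <- attr(rows[[1]], "class_of")
    out[[v]] <- tab
  }
  out
}

# Fit-and-score every (voi x variant x task) cell for one train/test split.
score_split <- function(prep, surv, train_idx, test_idx, config) {
  ranges <- vapply(prep[train_idx], `[[`, numeric(1), "voi14_range")
  bw <- determine_bin_width(ranges[is.finite(ranges)], config$n_bins)
  binning <- binning_spec(bw, config$n_bins, config$anchor)
  feats <- extract_prepared(prep, binning, config$classes, config$vois)
  ids <- vapply(prep, `[[`, character(1), "id")
  rows <- list()
  for (v in config$vois) {
    tab <- feats[[v]]
    class_of <- attr(tab, "class_of")
    tr_ids <- intersect(ids[train_idx], tab$subject_id)
    te_ids <- intersect(ids[test_idx], tab$subject_id)
    tr_tab <- tab[match(tr_ids, tab$subject_id), , drop = FALSE]
    te_tab <- tab[match(te_ids, tab$subject_id), , drop = FALSE]
    attr(tr_tab, "class_of") <- class_of
    dv <- tryCatch(
      build_dataset_variants(tr_tab, class_of, te_tab,
                             config$variance_target, config$per_component),
      error = function(e) e)
    for (var_name in config$variants) {
      for (task in config$tasks) {
        cell <- list(voi = v, variant = var_name, task = task,
                     value = NA_real_, note = "")
        if (inherits(dv, "error")) {
          cell$note <- conditionMessage(dv)
        } else {
          res <- tryCatch({
            spec <- config$rf_spec
            spec$seed <- derive_seed(config$seed, paste(v, var_name, task))
            tp <- train_and_predict(task, dv$train[[var_name]]$matrix,
                                    dv$test[[var_name]]$matrix,
                                    surv[match(tr_ids, surv$subject_id), ],
                                    surv[match(te_ids, surv$subject_id), ],
                                    spec)
            unname(tp$metric)
          }, error = function(e) e)
          if (inherits(res, "error")) cell$note <- conditionMessage(res)
          else cell$value <- res
        }
        rows <- c(rows, list(cell))
      }
    }
  }
  list(cells = do.call(rbind, lapply(rows, function(x)
    data.frame(voi = x$voi, variant = x$variant, task = x$task,
               value = x$value, note = x$note))),
    bin_width = bw)
}

default_eval_config <- function(seed = 1L) {
  list(thresholds = c(1.4, 1.6, 1.8), n_bins = 64, anchor = "voi_minimum",
       classes = names(feature_class_counts()),
       vois = c("voi14", "voi16", "voi18", "ptv"),
       variants = c("Top", "PC", "PC(SH-FO)", "SH-FO"),
       tasks = c("classify_1yr", "regress_days"),
       variance_target = 0.95, per_component = 10,
       rf_spec = rf_search_spec(), highlight = 0.65, seed = as.integer(seed))
}

#' Run one testing scenario over the full evaluation grid
#'
#' For every cell of VOIs x dataset variants x tasks, fits the bin width,
#' standardizer, PCA and tuned random forest on the training portion only
#' and scores the held-out portion (AUC for one-year classification,
#' C-index for survival-time regression). In the `combined_cv` scenario the
#' whole stack is refitted inside each fold and cell values are averaged
#' over folds. Failed cells are recorded with a note, never fatal.
#'
#' @param scenario a [scenario_spec()].
#' @param cohort a `phantom_cohort` (both scanner labels required for the
#'   independent scenario).
#' @param config named list as produced by the defaults (see
#'   [run_pipeline()]); entries: `thresholds`, `n_bins`, `anchor`,
#'   `classes`, `vois`, `variants`, `tasks`, `variance_target`,
#'   `per_component`, `rf_spec`, `highlight`, `seed`.
#' @param prep optional pre-segmented subject cache (internal reuse).
#' @return An `evaluation_report` data.frame with columns `scenario`, `voi`,
#'   `variant`, `task`, `metric`, `value`, `highlight` and `note`.
#' @export
run_scenario <- function(scenario, cohort, config = NULL, prep = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  cfg <- default_eval_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (is.null(prep)) prep <- prepare_subject_data(cohort, cfg$thresholds)
  surv <- cohort$survival
  scanners <- vapply(prep, `[[`, character(1), "scanner")
  if (scenario$name == "independent") {
    train_idx <- which(scanners == scenario$train_scanner)
    test_idx <- which(scanners == scenario$test_scanner)
    if (length(train_idx) == 0 || length(test_idx) == 0) {
      stop("run_scenario: cohort lacks one of the scanner labels")
    }
    sp <- score_split(prep, surv, train_idx, test_idx, cfg)
    cells <- sp$cells
  } else {
    set.seed(scenario$seed)
    fold <- sample(rep_len(seq_len(scenario$folds), length(prep)))
    per_fold <- lapply(seq_len(scenario$folds), function(f) {
      sp <- score_split(prep, surv, which(fold != f), which(fold == f), cfg)
      sp$cells
    })
    cells <- per_fold[[1]][, c("voi", "variant", "task")]
    vals <- sapply(per_fold, function(x) x$value)
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    cells$value <- rowMeans(vals, na.rm = TRUE)
    cells$value[!is.finite(cells$value)] <- NA_real_
    notes <- sapply(per_fold, function(x) x$note)
    if (is.null(dim(notes))) notes <- matrix(notes, nrow = 1)
    cells$note <- apply(notes, 1, function(x) paste(unique(x[nzchar(x)]),
                                                    collapse = "; "))
    attr(cells, "fold_assignment") <- fold
  }
  cells$metric <- ifelse(cells$task == "classify_1yr", "AUC", "C-index")
  cells$highlight <- !is.na(cells$value) & cells$value > cfg$highlight
  out <- cbind(scenario = scenario$name,
               cells[, c("voi", "variant", "task", "metric", "value",
                         "highlight", "note")])
  attr(out, "fold_assignment") <- attr(cells, "fold_assignment")
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Univariate Cox screen over a dataset variant, per VOI
#'
#' Fits a univariate Cox model to every column of the given dataset variant
#' in every VOI and reports coefficient, hazard ratio and Wald p-value,
#' flagging features significant at `alpha`.
#'
#' @param datasets named list (by VOI) of `dataset_variant`s (typically the
#'   Top variant).
#' @param surv survival data.frame with `subject_id`, `time_days`, `event`
#'   rows matching the variant matrices.
#' @param alpha significance level (default 0.05, no multiplicity
#'   correction; set `adjust = "BH"` for a Benjamini-Hochberg variant).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per (voi, feature).
#' @export
univariate_screen_report <- function(datasets, surv, alpha = 0.05,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- list()
  for (v in names(datasets)) {
    m <- datasets[[v]]$matrix
    if (is.null(m) || ncol(m) == 0) next
    ids <- rownames(m)
    sv <- surv[match(ids, surv$subject_id), ]
    for (f in colnames(m)) {
      cf <- fit_univariate_cox(m[, f], sv$time_days, sv$event, alpha)
      rows <- c(rows, list(data.frame(
        voi = v, feature = f, coef = cf$coef, hazard_ratio = cf$hazard_ratio,
        p_value = cf$p_value, converged = cf$converged)))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(voi = character(0), feature = character(0),
                      coef = numeric(0), hazard_ratio = numeric(0),
                      p_value = numeric(0), converged = logical(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  p <- out$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  out$significant <- out$converged & !is.na(p) & p < alpha
  out
}
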