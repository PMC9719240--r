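# Run configuration and end-to-end pipeline: phantom cohort -> segmentation
# -> feature extraction -> dataset variants -> survival models -> report.

#' Build a run configuration
#'
#' A serializable description of a full pipeline run: cohort design,
#' survival link, segmentation thresholds, binning, PCA target, random
#' forest search settings and scenario list. Every stochastic stage derives
#' its own seed from the single global `seed`.
#'
#' @param n_train,n_test cohort sizes for the two scanner profiles.
#' @param train_grid,test_grid reconstruction grid shapes (voxels).
#' @param tumor_ranges named list overriding the cohort sampling ranges
#'   (see [cohort_spec()]).
#' @param ptv_margin PTV dilation margin, mm.
#' @param baseline_hazard,coefficients,centers survival link parameters
#'   (see [survival_link()]).
#' @param thresholds TBR segmentation thresholds.
#' @param n_bins reference bin number for the fixed bin width.
#' @param anchor discretization anchor.
#' @param variance_target PCA explained-variance target.
#' @param per_component Top-dataset features per component.
#' @param classes feature classes to extract.
#' @param vois,variants,tasks evaluation grid axes.
#' @param scenarios character vector among `"independent"`, `"combined_cv"`.
#' @param folds combined-CV fold count.
#' @param n_settings,cv_folds,class_weights random-forest search settings.
#' @param highlight report highlighting threshold.
#' @param out_dir output directory (`NULL` = no files written).
#' @param seed global integer seed.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(n_train = 25, n_test = 12,
                       train_grid = c(72L, 72L, 56L),
                       test_grid = c(144L, 144L, 64L),
                       tumor_ranges = list(), ptv_margin = 20,
                       baseline_hazard = 1 / 450,
                       coefficients = c(major_axis_mm = 0.10),
                       centers = c(major_axis_mm = 42),
                       thresholds = c(1.4, 1.6, 1.8),
                       n_bins = 64, anchor = "voi_minimum",
                       variance_target = 0.95, per_component = 10,
                       classes = names(feature_class_counts()),
                       vois = c("voi14", "voi16", "voi18", "ptv"),
                       variants = c("Top", "PC", "PC(SH-FO)", "SH-FO"),
                       tasks = c("classify_1yr", "regress_days"),
                       scenarios = c("independent", "combined_cv"),
                       folds = 5, n_settings = 15, cv_folds = 5,
                       class_weights = "balanced", highlight = 0.65,
                       out_dir = NULL, seed = 1L) {
  cfg <- list(n_train = n_train, n_test = n_test,
              train_grid = as.integer(train_grid),
              test_grid = as.integer(test_grid),
              tumor_ranges = tumor_ranges, ptv_margin = ptv_margin,
              baseline_hazard = baseline_hazard,
              coefficients = as.list(coefficients), centers = as.list(centers),
              thresholds = thresholds, n_bins = n_bins, anchor = anchor,
              variance_target = variance_target, per_component = per_component,
              classes = classes, vois = vois, variants = variants,
              tasks = tasks, scenarios = scenarios, folds = folds,
              n_settings = n_settings, cv_folds = cv_folds,
              class_weights = class_weights, highlight = highlight,
              out_dir = out_dir, seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$thresholds) || length(cfg$thresholds) == 0) {
    stop("run_config: thresholds must be a nonempty numeric vector")
  }
  if (any(cfg$thresholds <= 1)) stop("run_config: TBR thresholds must exceed 1")
  stopifnot(cfg$n_train >= 2, cfg$n_test >= 2, cfg$n_bins >= 2,
            cfg$variance_target > 0, cfg$variance_target <= 1,
            cfg$ptv_margin > 0, cfg$folds >= 2)
  if (!all(cfg$scenarios %in% c("independent", "combined_cv"))) {
    stop("run_config: unknown scenario name")
  }
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' `load_run_config(save_run_config(cfg, path))` reproduces the
#' configuration (validated on load).
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   returns a `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("thresholds", "classes", "vois", "variants", "tasks", "scenarios")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  for (nm in c("train_grid", "test_grid")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(unlist(cfg[[nm]]))
  }
  validate_run_config(cfg)
}

#' Run the full pipeline from a configuration
#'
#' Generates the two-profile phantom cohort, segments all VOIs, runs every
#' configured scenario over the VOI x variant x task grid, screens the Top
#' datasets with univariate Cox models, and (optionally) writes
#' `report.csv`, `report.json`, `screen.csv` and `selection_frequency.csv`
#' to `out_dir`. Identical configuration and seed reproduce the report
#' byte-identically.
#'
#' @param cfg a [run_config()].
#' @return List with `report` (stacked `evaluation_report`), `screen`
#'   (univariate Cox table), `selection` (Top-dataset selection
#'   frequencies), `bin_width`, `cohort` and `config`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  link <- survival_link(baseline_hazard = cfg$baseline_hazard,
                        coefficients = unlist(cfg$coefficients),
                        centers = unlist(cfg$centers),
                        seed = derive_seed(cfg$seed, "link"))
  cohort <- generate_study_cohort(
    n_train = cfg$n_train, n_test = cfg$n_test, link = link,
    seed = derive_seed(cfg$seed, "cohort"),
    train_profile = profile_osem2d(grid_shape = cfg$train_grid),
    test_profile = profile_osem3d(grid_shape = cfg$test_grid),
    tumor_ranges = cfg$tumor_ranges, ptv_margin = cfg$ptv_margin)
  prep <- prepare_subject_data(cohort, cfg$thresholds)

  eval_cfg <- list(thresholds = cfg$thresholds, n_bins = cfg$n_bins,
                   anchor = cfg$anchor, classes = cfg$classes,
                   vois = cfg$vois, variants = cfg$variants,
                   tasks = cfg$tasks, variance_target = cfg$variance_target,
                   per_component = cfg$per_component,
                   rf_spec = rf_search_spec(n_settings = cfg$n_settings,
                                            cv_folds = cfg$cv_folds,
                                            class_weights = cfg$class_weights,
                                            seed = derive_seed(cfg$seed, "rf")),
                   highlight = cfg$highlight,
                   seed = derive_seed(cfg$seed, "eval"))
  reports <- list()
  for (sc in cfg$scenarios) {
    spec <- scenario_spec(sc, folds = cfg$folds,
                          seed = derive_seed(cfg$seed, paste0("scenario_", sc)))
    reports[[sc]] <- run_scenario(spec, cohort, eval_cfg, prep)
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL

  # univariate screen on the Top datasets: models fitted on the training
  # scanner, Cox fits over the full cohort
  scanners <- vapply(prep, `[[`, character(1), "scanner")
  train_idx <- which(scanners == cohort$scanner$train$name)
  rng <- vapply(prep[train_idx], `[[`, numeric(1), "voi14_range")
  bw <- determine_bin_width(rng[is.finite(rng)], cfg$n_bins)
  binning <- binning_spec(bw, cfg$n_bins, cfg$anchor)
  feats <- extract_prepared(prep, binning, cfg$classes, cfg$vois)
  tops <- list()
  for (v in cfg$vois) {
    tab <- feats[[v]]
    class_of <- attr(tab, "class_of")
    tr_tab <- tab[tab$subject_id %in% cohort$survival$subject_id[
      cohort$survival$scanner == cohort$scanner$train$name], , drop = FALSE]
    std <- fit_standardizer(tr_tab)
    pca <- fit_pca(apply_standardizer(std, tr_tab), cfg$variance_target)
    tops[[v]] <- build_top(pca, apply_standardizer(std, tab), cfg$per_component)
  }
  screen <- univariate_screen_report(tops, cohort$survival)
  class_of <- attr(feats[[1]], "class_of")
  selection <- selection_frequency(tops, class_of)

  out <- list(report = report, screen = screen, selection = selection,
              bin_width = bw, cohort = cohort, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(cfg$out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report[, c("scenario", "voi", "variant", "task",
                                    "metric", "value", "highlight")],
                         file.path(cfg$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
    utils::write.csv(screen, file.path(cfg$out_dir, "screen.csv"),
                     row.names = FALSE)
    utils::write.csv(selection, file.path(cfg$out_dir, "selection_frequency.csv"),
                     row.names = FALSE)
  }
  out
}
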