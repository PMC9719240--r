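# Univariate Cox screening, Kaplan-Meier median-split stratification, and
# random-forest survival prediction with coarse-to-fine randomized
# hyperparameter search.

#' Univariate Cox proportional-hazards fit for one feature
#'
#' Wraps a single-covariate Cox partial-likelihood fit (Efron tie handling)
#' and reports the Wald p-value; a feature is flagged significant at the 5%
#' level. Non-converged or degenerate fits are flagged and never counted as
#' significant.
#'
#' @param x numeric feature values.
#' @param time survival times in days (> 0).
#' @param event event indicators (1 = death observed).
#' @param alpha significance threshold (default 0.05).
#' @return An object of class `cox_fit`: `coef`, `hazard_ratio`, `se`,
#'   `p_value`, `significant`, `converged`, `n`.
#' @export
fit_univariate_cox <- function(x, time, event, alpha = 0.05) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (length(x) < 10) stop("fit_univariate_cox: need n >= 10")
  if (any(time <= 0)) stop("fit_univariate_cox: all times must be positive")
  if (stats::sd(x) == 0) {
    return(structure(list(coef = 0, hazard_ratio = 1, se = NA_real_,
                          p_value = 1, significant = FALSE, converged = FALSE,
                          n = length(x)), class = "cox_fit"))
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x,
                                     ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit) || is.na(stats::coef(fit)[1])) {
    return(structure(list(coef = NA_real_, hazard_ratio = NA_real_,
                          se = NA_real_, p_value = NA_real_,
                          significant = FALSE, converged = FALSE,
                          n = length(x)), class = "cox_fit"))
  }
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  converged <- is.finite(b) && is.finite(se) && se < 50
  structure(list(coef = b, hazard_ratio = exp(b), se = se, p_value = p,
                 significant = converged && p < alpha, converged = converged,
                 n = length(x)), class = "cox_fit")
}

#' Kaplan-Meier stratification at the feature median
#'
#' Splits subjects at the median feature value (ties to the lower group),
#' estimates the product-limit survival curve per group and compares the
#' groups with the two-sample log-rank test.
#'
#' @param x numeric feature values (nonconstant).
#' @param time survival times in days.
#' @param event event indicators.
#' @return An object of class `km_stratification`: `split_value`, `group`
#'   (factor low/high), `fit` (a [survival::survfit] object), `chisq`,
#'   `p_value`.
#' @export
km_median_split <- function(x, time, event) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (length(x) < 4) stop("km_median_split: need n >= 4")
  med <- stats::median(x)
  grp <- factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
  if (nlevels(droplevels(grp)) < 2) {
    stop("km_median_split: feature is constant (or median splits nothing)")
  }
  sv <- survival::Surv(time, event)
  fit <- survival::survfit(sv ~ grp)
  sd_ <- survival::survdiff(sv ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  structure(list(split_value = med, group = grp, fit = fit,
                 chisq = unname(sd_$chisq), p_value = p),
            class = "km_stratification")
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (ties counted half),
#' so it is invariant under strictly monotone transforms of the scores.
#'
#' @param labels binary labels (0/1).
#' @param scores predicted scores for the positive class.
#' @return AUC in [0, 1], or `NA` if only one class is present.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance index for survival-time predictions
#'
#' The fraction of comparable subject pairs whose predicted and observed
#' orderings agree (ties in prediction count half). With complete follow-up
#' (all events observed) every pair with distinct event times is comparable;
#' with censoring, a pair is comparable only if the earlier time is an
#' event.
#'
#' @param time observed survival times.
#' @param event event indicators.
#' @param predicted predicted survival times (higher = longer survival).
#' @return C-index in [0, 1], or `NA` with no comparable pairs.
#' @export
concordance_index <- function(time, event, predicted) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      first <- if (time[i] < time[j]) i else j
      if (event[first] != 1) next  # earlier time censored: not comparable
      second <- if (first == i) j else i
      den <- den + 1
      if (predicted[first] < predicted[second]) num <- num + 1
      else if (predicted[first] == predicted[second]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Randomized-search specification for the random forests
#'
#' Two-stage coarse-to-fine search: stage 1 samples hyperparameter settings
#' log-uniformly from broad ranges to locate the right order of magnitude;
#' stage 2 resamples within a multiplicative window around the stage-1
#' winner. Cross-validated AUC (classification) or C-index (regression)
#' scores each setting.
#'
#' @param task `"classify_1yr"` or `"regress_days"`.
#' @param n_trees_range,min_node_range broad ranges (log scale).
#' @param mtry_frac_range fraction of features tried per split.
#' @param refine_factor multiplicative half-width of the stage-2 window.
#' @param cv_folds folds of the inner cross-validation.
#' @param n_settings settings sampled per stage.
#' @param class_weights `"balanced"` or `"none"` (classification only).
#' @param seed integer seed.
#' @return An object of class `rf_search_spec`.
#' @export
rf_search_spec <- function(task = c("classify_1yr", "regress_days"),
                           n_trees_range = c(50, 1000),
                           min_node_range = c(1, 16),
                           mtry_frac_range = c(0.1, 1),
                           refine_factor = 2, cv_folds = 5, n_settings = 50,
                           class_weights = c("balanced", "none"), seed = 1L) {
  task <- match.arg(task)
  class_weights <- match.arg(class_weights)
  stopifnot(cv_folds >= 2, n_settings >= 1, refine_factor > 1)
  structure(list(task = task, n_trees_range = n_trees_range,
                 min_node_range = min_node_range,
                 mtry_frac_range = mtry_frac_range,
                 refine_factor = refine_factor, cv_folds = cv_folds,
                 n_settings = n_settings, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "rf_search_spec")
}

sample_settings <- function(n, trees_r, node_r, mtry_r, p) {
  data.frame(
    num_trees = pmax(10L, as.integer(round(exp(stats::runif(n, log(trees_r[1]), log(trees_r[2])))))),
    min_node = pmax(1L, as.integer(round(exp(stats::runif(n, log(node_r[1]), log(node_r[2])))))),
    mtry = pmin(p, pmax(1L, as.integer(round(
      exp(stats::runif(n, log(mtry_r[1] * p), log(mtry_r[2] * p))))))))
}

fit_rf <- function(X, y, task, setting, class_weights, seed) {
  df <- as.data.frame(X)
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  if (task == "classify_1yr") {
    yf <- factor(y, levels = c(0, 1))
    cw <- if (class_weights == "balanced") {
      tb <- table(yf)
      w <- as.numeric(length(yf) / (2 * pmax(tb, 1)))
      names(w) <- names(tb)
      w
    } else NULL
    ranger::ranger(x = df, y = yf, probability = TRUE,
                   num.trees = setting$num_trees, mtry = setting$mtry,
                   min.node.size = setting$min_node, class.weights = cw,
                   seed = seed, num.threads = 1)
  } else {
    ranger::ranger(x = df, y = as.numeric(y),
                   num.trees = setting$num_trees, mtry = setting$mtry,
                   min.node.size = setting$min_node,
                   seed = seed, num.threads = 1)
  }
}

predict_rf <- function(model, X, task) {
  df <- as.data.frame(X)
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  pr <- stats::predict(model, data = df, num.threads = 1)
  if (task == "classify_1yr") pr$predictions[, "1"] else pr$predictions
}

# Score one setting by cross-validation over a fixed fold assignment. The
# forest seed is keyed on the setting values and fold (not the sampling
# order), so re-evaluating an identical setting reproduces its score.
cv_score <- function(X, y, event, task, setting, class_weights, fold, seed0) {
  scores <- numeric(0)
  key <- paste("rf", setting$num_trees, setting$min_node, setting$mtry)
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (task == "classify_1yr" && length(unique(y[tr])) < 2) next
    mod <- fit_rf(X[tr, , drop = FALSE], y[tr], task, setting, class_weights,
                  derive_seed(seed0 + f, key))
    pred <- predict_rf(mod, X[te, , drop = FALSE], task)
    sc <- if (task == "classify_1yr") auc_score(y[te], pred)
          else concordance_index(y[te], event[te], pred)
    if (!is.na(sc)) scores <- c(scores, sc)
  }
  if (length(scores) == 0) NA_real_ else mean(scores)
}

#' Coarse-to-fine randomized hyperparameter search
#'
#' @param spec an [rf_search_spec()].
#' @param X feature matrix (subjects x features).
#' @param y response: 0/1 one-year labels (classification) or survival days
#'   (regression).
#' @param event event indicators (used by the regression C-index).
#' @return List with `best` (chosen setting), `best_score`, and `trace`
#'   (data.frame of all evaluated settings and scores, with a `stage`
#'   column).
#' @export
coarse_to_fine_search <- function(spec, X, y, event = rep(1, length(y))) {
  stopifnot(inherits(spec, "rf_search_spec"))
  X <- as.matrix(X)
  if (spec$task == "classify_1yr" && length(unique(y)) < 2) {
    stop("coarse_to_fine_search: degenerate response (single class)")
  }
  p <- ncol(X)
  set.seed(derive_seed(spec$seed, "folds"))
  fold <- sample(rep_len(seq_len(spec$cv_folds), nrow(X)))
  run_stage <- function(settings, stage) {
    settings$score <- NA_real_
    for (i in seq_len(nrow(settings))) {
      settings$score[i] <- cv_score(X, y, event, spec$task, settings[i, ],
                                    spec$class_weights, fold, spec$seed)
    }
    settings$stage <- stage
    settings
  }
  set.seed(spec$seed)
  s1 <- sample_settings(spec$n_settings, spec$n_trees_range,
                        spec$min_node_range, spec$mtry_frac_range, p)
  s1 <- run_stage(s1, 1L)
  if (all(is.na(s1$score))) {
    stop("coarse_to_fine_search: no scorable CV fold (degenerate labels?)")
  }
  b1 <- s1[which.max(s1$score), ]
  rf <- spec$refine_factor
  set.seed(derive_seed(spec$seed, "refine"))
  s2 <- sample_settings(spec$n_settings,
                        c(b1$num_trees / rf, b1$num_trees * rf),
                        c(max(1, b1$min_node / rf), b1$min_node * rf),
                        c(max(1 / p, b1$mtry / (rf * p)),
                          min(1, b1$mtry * rf / p)), p)
  # the stage-1 winner re-enters the refined grid, so (with the shared fold
  # assignment and setting-keyed seeds) refinement can never lose ground
  s2 <- rbind(b1[, c("num_trees", "min_node", "mtry")], s2)
  s2 <- run_stage(s2, 2L)
  trace <- rbind(s1, s2)
  best <- s2[which.max(s2$score), ]
  list(best = best[, c("num_trees", "min_node", "mtry")],
       best_score = best$score, trace = trace)
}

#' Train the tuned forest and score it on held-out subjects
#'
#' Runs the coarse-to-fine search on the training subjects, fits the final
#' model with the chosen hyperparameters, and reports the test metric:
#' AUC of the one-year survival probability (classification) or C-index of
#' the predicted survival days (regression).
#'
#' @param task `"classify_1yr"` or `"regress_days"`.
#' @param X_train,X_test feature matrices.
#' @param surv_train,surv_test survival data.frames with `time_days`,
#'   `event`, `label_1yr`.
#' @param spec an [rf_search_spec()] (its `task` is overridden by `task`).
#' @return List with `model` (the fitted forest), `chosen` (hyperparameters),
#'   `metric` (named test AUC or C-index, `NA` when undefined, e.g. a
#'   single-class test set), `predictions`.
#' @export
train_and_predict <- function(task, X_train, X_test, surv_train, surv_test,
                              spec = rf_search_spec()) {
  spec$task <- task
  y_tr <- if (task == "classify_1yr") surv_train$label_1yr else surv_train$time_days
  srch <- coarse_to_fine_search(spec, X_train, y_tr, surv_train$event)
  model <- fit_rf(as.matrix(X_train), y_tr, task, srch$best, spec$class_weights,
                  derive_seed(spec$seed, "final"))
  pred <- predict_rf(model, as.matrix(X_test), task)
  metric <- if (task == "classify_1yr") {
    c(auc = auc_score(surv_test$label_1yr, pred))
  } else {
    c(cindex = concordance_index(surv_test$time_days, surv_test$event, pred))
  }
  list(model = model, chosen = srch$best, search = srch,
       metric = metric, predictions = pred)
}
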