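#' Feature class sizes of the default 107-feature set
#'
#' @return Named integer vector: FO 18, SH 14, GLCM 24, GLRLM 16, GLSZM 16,
#'   NGTDM 5, GLDM 14.
#' @export
feature_class_counts <- function() {
  c(FO = 18L, SH = 14L, GLCM = 24L, GLRLM = 16L, GLSZM = 16L,
    NGTDM = 5L, GLDM = 14L)
}

#' Extract the radiomic feature vector of one VOI
#'
#' Discretizes the VOI intensities with the fixed bin width, builds the five
#' gray-level texture matrices, and computes the requested feature classes.
#' With all classes enabled the result has exactly 107 features; shape plus
#' first order alone give 32. Degenerate VOIs (constant intensity, single
#' voxel) produce documented default values, never missing entries.
#'
#' @param image a [pet_volume()].
#' @param mask a [voi_mask()] aligned to `image`.
#' @param binning a [binning_spec()].
#' @param classes character vector of feature classes to compute (subset of
#'   `names(feature_class_counts())`, default all).
#' @param aggregation direction aggregation for GLCM/GLRLM features
#'   (`"mean"` or `"merged"`, see [glcm_features()]).
#' @return An object of class `feature_vector`: a named numeric vector with
#'   attributes `class_of` (named class map), `voi_origin` and `binning`.
#' @export
extract_features <- function(image, mask, binning = binning_spec(),
                             classes = names(feature_class_counts()),
                             aggregation = "mean") {
  stopifnot(inherits(image, "pet_volume"), inherits(mask, "voi_mask"),
            inherits(binning, "binning_spec"))
  check_aligned(image, mask)
  if (mask$n_voxels < 1L) stop(empty_voi_error("extract_features: empty VOI"))
  bad <- setdiff(classes, names(feature_class_counts()))
  if (length(bad) > 0) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  values <- image$data[mask$mask]
  lev_vec <- discretize(values, binning$bin_width, binning$anchor)
  lev_arr <- array(NA_integer_, dim(mask$mask))
  lev_arr[mask$mask] <- lev_vec
  parts <- list()
  if ("FO" %in% classes) {
    parts$FO <- first_order_features(values, lev_vec, image$spacing)
  }
  if ("SH" %in% classes) {
    parts$SH <- shape_features(mask$mask, image$spacing)
  }
  tex <- intersect(classes, c("GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM"))
  if (length(tex) > 0) {
    tm <- compute_texture_matrices(lev_arr, mask$mask)
    if ("GLCM" %in% tex) parts$GLCM <- glcm_features(tm, aggregation)
    if ("GLRLM" %in% tex) parts$GLRLM <- glrlm_features(tm, aggregation)
    if ("GLSZM" %in% tex) parts$GLSZM <- glszm_features(tm)
    if ("NGTDM" %in% tex) parts$NGTDM <- ngtdm_features(tm)
    if ("GLDM" %in% tex) parts$GLDM <- gldm_features(tm)
  }
  ord <- intersect(names(feature_class_counts()), names(parts))
  out <- unlist(parts[ord])
  names(out) <- sub("^[A-Z]+\\.", "", names(out))  # strip list-prefix, keep class prefix
  class_of <- rep(ord, times = vapply(parts[ord], length, integer(1)))
  names(class_of) <- names(out)
  if (any(!is.finite(out))) {
    stop("extract_features: non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  structure(out, class_of = class_of, voi_origin = mask$origin,
            binning = binning, class = c("feature_vector", "numeric"))
}

#' Extract features for every subject and VOI of a cohort
#'
#' Segments each subject (voi14/voi16/voi18 + PTV) and extracts the feature
#' vector per VOI with a common, frozen binning specification.
#'
#' @param cohort a `phantom_cohort`.
#' @param binning a [binning_spec()]; typically built from
#'   [determine_bin_width()] on the training subjects' voi14 ranges.
#' @param classes feature classes to compute.
#' @param thresholds TBR thresholds for the PET-based VOIs.
#' @param vois which VOIs to keep (default all four).
#' @return A named list (by VOI) of feature tables: data.frames with
#'   `subject_id` followed by feature columns; attribute `class_of` carries
#'   the feature-class map.
#' @export
extract_cohort_features <- function(cohort, binning,
                                    classes = names(feature_class_counts()),
                                    thresholds = c(1.4, 1.6, 1.8),
                                    vois = c("voi14", "voi16", "voi18", "ptv")) {
  tabs <- list()
  for (s in cohort$subjects) {
    bg <- estimate_background(s$volume, "provided_mask",
                              background_mask = s$background_mask)
    tbr_vol <- pet_volume(s$volume$data / bg, s$volume$spacing, s$volume$profile)
    seed_point <- round(colMeans(arrayInd(which(s$tumor_mask), dim(s$tumor_mask))))
    masks <- segment_tbr_set(tbr_vol, 1, seed_point, thresholds)
    masks$ptv <- s$ptv
    for (v in intersect(vois, names(masks))) {
      fv <- extract_features(tbr_vol, masks[[v]], binning, classes)
      row <- data.frame(subject_id = s$id, t(as.numeric(fv)))
      colnames(row) <- c("subject_id", names(fv))
      tabs[[v]] <- c(tabs[[v]], list(row))
      if (is.null(attr(tabs, paste0("class_of_", v)))) {
        attr(tabs, paste0("class_of_", v)) <- attr(fv, "class_of")
      }
    }
  }
  out <- lapply(tabs, function(rows) do.call(rbind, rows))
  for (v in names(out)) {
    attr(out[[v]], "class_of") <- attr(tabs, paste0("class_of_", v))
  }
  out
}

#' Per-subject voi14 intensity ranges (for bin-width calibration)
#'
#' @param cohort a `phantom_cohort`.
#' @param subject_ids restrict to these subjects (default all; pass the
#'   training ids to respect the train-only calibration contract).
#' @param threshold TBR threshold of the calibration VOI (default 1.4).
#' @return Numeric vector of per-subject intensity ranges (max - min of the
#'   TBR values inside the threshold VOI).
#' @export
voi14_intensity_ranges <- function(cohort, subject_ids = NULL, threshold = 1.4) {
  ids <- vapply(cohort$subjects, function(s) s$id, character(1))
  keep <- if (is.null(subject_ids)) seq_along(ids) else match(subject_ids, ids)
  vapply(cohort$subjects[keep], function(s) {
    bg <- estimate_background(s$volume, "provided_mask",
                              background_mask = s$background_mask)
    seed_point <- round(colMeans(arrayInd(which(s$tumor_mask), dim(s$tumor_mask))))
    m <- segment_tbr(s$volume, bg, threshold, seed_point)
    vals <- s$volume$data[m$mask] / bg
    diff(range(vals))
  }, numeric(1))
}
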