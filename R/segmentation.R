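#' Empty-VOI condition
#'
#' Segmentation and PTV cleaning signal an empty result through a classed
#' condition rather than returning a silent empty mask.
#'
#' @param message condition message.
#' @keywords internal
empty_voi_error <- function(message) {
  structure(class = c("fetrad_empty_voi", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

#' Estimate the background uptake level
#'
#' The TBR denominator: mean (or median) image intensity over a healthy
#' reference region, given either as an explicit mask (`mode =
#' "provided_mask"`, the default; phantom cohorts emit one) or as a
#' spherical shell around a reference point (`mode = "contralateral_shell"`),
#' a deterministic stand-in for crescent-shaped contralateral background
#' regions drawn in clinical workflows.
#'
#' @param image a [pet_volume()].
#' @param mode background definition mode.
#' @param background_mask logical array (required for `provided_mask`).
#' @param center_vox voxel triplet at the shell centre (for shell mode).
#' @param shell_inner,shell_outer shell radii in mm, `0 < inner < outer`.
#' @param statistic `"mean"` or `"median"`.
#' @return Scalar background level (> 0).
#' @export
estimate_background <- function(image,
                                mode = c("provided_mask", "contralateral_shell"),
                                background_mask = NULL, center_vox = NULL,
                                shell_inner = 30, shell_outer = 50,
                                statistic = c("mean", "median")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (mode == "provided_mask") {
    if (is.null(background_mask)) stop("estimate_background: background_mask required")
    if (!identical(dim(background_mask), dim(image$data))) {
      stop("estimate_background: background mask grid mismatch")
    }
    vals <- image$data[background_mask]
  } else {
    if (is.null(center_vox)) stop("estimate_background: center_vox required for shell mode")
    if (!(shell_outer > shell_inner && shell_inner > 0)) {
      stop("estimate_background: need 0 < shell_inner < shell_outer")
    }
    d <- dim(image$data)
    sp <- image$spacing
    ax <- lapply(1:3, function(i) (seq_len(d[i]) - center_vox[i]) * sp[i])
    r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    vals <- image$data[r2 >= shell_inner^2 & r2 <= shell_outer^2]
  }
  if (length(vals) == 0) stop("estimate_background: empty background region")
  bg <- if (statistic == "mean") mean(vals) else stats::median(vals)
  if (!is.finite(bg) || bg <= 0) stop("estimate_background: nonpositive background level")
  bg
}

#' Segment a TBR-thresholded volume of interest
#'
#' Divides the image by the background level, thresholds the TBR map at
#' `threshold`, and keeps the 26-connected component containing
#' `seed_point`. When the seed itself falls below threshold, the nearest
#' above-threshold component within `search_radius_mm` is used. An empty
#' result raises a classed `fetrad_empty_voi` condition.
#'
#' @param image a [pet_volume()].
#' @param background scalar background level (> 0).
#' @param threshold TBR threshold (> 1); 1.4, 1.6 and 1.8 are the
#'   conventional choices.
#' @param seed_point voxel triplet inside the grid.
#' @param search_radius_mm search radius for relocating an off-target seed.
#' @return A [voi_mask()] with origin `voi14`/`voi16`/`voi18` (derived from
#'   the threshold) or `voiXX` otherwise.
#' @export
segment_tbr <- function(image, background, threshold, seed_point,
                        search_radius_mm = 30) {
  stopifnot(inherits(image, "pet_volume"), background > 0, threshold > 1)
  d <- dim(image$data)
  seed_point <- as.integer(round(seed_point))
  if (any(seed_point < 1L) || any(seed_point > d)) {
    stop("segment_tbr: seed_point outside grid")
  }
  tbr <- image$data / background
  above <- tbr >= threshold
  if (!any(above)) {
    stop(empty_voi_error(sprintf("no voxel above TBR %.2f", threshold)))
  }
  lab <- label_components(above, connectivity = 26)
  target <- lab[seed_point[1], seed_point[2], seed_point[3]]
  if (target == 0L) {
    idx <- which(above)
    co <- arrayInd(idx, d)
    dmm2 <- ((co[, 1] - seed_point[1]) * image$spacing[1])^2 +
      ((co[, 2] - seed_point[2]) * image$spacing[2])^2 +
      ((co[, 3] - seed_point[3]) * image$spacing[3])^2
    j <- which.min(dmm2)
    if (sqrt(dmm2[j]) > search_radius_mm) {
      stop(empty_voi_error(sprintf(
        "no above-threshold voxel within %.0f mm of the seed", search_radius_mm)))
    }
    target <- lab[idx[j]]
  }
  origin <- if (abs(threshold * 10 - round(threshold * 10)) < 1e-9) {
    sprintf("voi%02d", as.integer(round(threshold * 10)))
  } else "voi"
  voi_mask(lab == target, origin, threshold, image$spacing)
}

#' Segment all three conventional TBR thresholds
#'
#' @param image a [pet_volume()].
#' @param background scalar background level.
#' @param seed_point voxel triplet.
#' @param thresholds TBR thresholds (default 1.4, 1.6, 1.8).
#' @param ... passed to [segment_tbr()].
#' @return Named list of [voi_mask()]s (`voi14`, `voi16`, `voi18`).
#' @export
segment_tbr_set <- function(image, background, seed_point,
                            thresholds = c(1.4, 1.6, 1.8), ...) {
  out <- lapply(thresholds, function(th)
    segment_tbr(image, background, th, seed_point, ...))
  names(out) <- vapply(out, function(m) m$origin, character(1))
  out
}

#' Remove excluded structures from a PTV mask
#'
#' Emulates the planning step in which high-density structures (e.g. bone)
#' that carry no tracer-uptake information are excluded from the planning
#' target volume before feature extraction.
#'
#' @param ptv a [voi_mask()].
#' @param exclusion optional logical array on the same grid; voxels in it are
#'   removed from the PTV.
#' @return A [voi_mask()]; raises `fetrad_empty_voi` if nothing remains.
#' @export
clean_ptv <- function(ptv, exclusion = NULL) {
  stopifnot(inherits(ptv, "voi_mask"))
  if (is.null(exclusion)) return(ptv)
  if (!identical(dim(exclusion), dim(ptv$mask))) {
    stop(sprintf("clean_ptv: grid mismatch: ptv %s vs exclusion %s",
                 paste(dim(ptv$mask), collapse = "x"),
                 paste(dim(exclusion), collapse = "x")))
  }
  m <- ptv$mask & !exclusion
  if (!any(m)) stop(empty_voi_error("clean_ptv: exclusion removed the entire PTV"))
  voi_mask(m, ptv$origin, ptv$threshold, ptv$spacing)
}

#' Segment the full VOI set for one phantom subject
#'
#' Estimates the background from the subject's emitted background mask,
#' segments voi14/voi16/voi18 seeded at the true tumor centre-of-mass, and
#' attaches the (cleaned) PTV mask.
#'
#' @param subject one element of a `phantom_cohort`'s `subjects` list.
#' @param thresholds TBR thresholds.
#' @param exclusion optional exclusion mask for the PTV.
#' @return Named list of [voi_mask()]s (`voi14`, `voi16`, `voi18`, `ptv`).
#' @export
segment_subject <- function(subject, thresholds = c(1.4, 1.6, 1.8),
                            exclusion = NULL) {
  bg <- estimate_background(subject$volume, "provided_mask",
                            background_mask = subject$background_mask)
  seed_point <- round(colMeans(arrayInd(which(subject$tumor_mask),
                                        dim(subject$tumor_mask))))
  vois <- segment_tbr_set(subject$volume, bg, seed_point, thresholds)
  vois$ptv <- clean_ptv(subject$ptv, exclusion)
  vois
}
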