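#' PET volume container
#'
#' A 3D scalar grid (tumor-to-background-ratio units by convention) with
#' anisotropic voxel spacing and a scanner-profile tag.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing voxel spacing in mm, length-3 positive numeric.
#' @param profile scanner profile label (free-form character).
#' @return An object of class `pet_volume` with elements `data`, `spacing`
#'   and `profile`.
#' @export
pet_volume <- function(data, spacing, profile = "unknown") {
  if (length(dim(data)) != 3L) stop("pet_volume: data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("pet_volume: spacing must be three positive numbers (mm)")
  }
  structure(list(data = data, spacing = spacing, profile = as.character(profile)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s, grid %s, spacing %s mm, TBR range [%.3f, %.3f]\n",
              x$profile, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Volume-of-interest mask
#'
#' A binary 3D mask aligned to a [pet_volume()], labelled by origin
#' (`voi14`, `voi16`, `voi18` or `ptv`).
#'
#' @param mask logical (or 0/1) 3D array.
#' @param origin one of `"voi14"`, `"voi16"`, `"voi18"`, `"ptv"` or another
#'   descriptive label.
#' @param threshold the TBR threshold the mask was derived from, or `NA`.
#' @param spacing voxel spacing in mm of the grid the mask lives on.
#' @return An object of class `voi_mask` with elements `mask`, `origin`,
#'   `threshold`, `spacing` and `n_voxels`.
#' @export
voi_mask <- function(mask, origin, threshold = NA_real_, spacing = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop("voi_mask: mask must be a 3D array")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("voi_mask: mask values must be binary (0/1)")
  }
  m <- array(as.logical(mask), dim(mask))
  structure(list(mask = m, origin = as.character(origin),
                 threshold = as.numeric(threshold),
                 spacing = as.numeric(spacing),
                 n_voxels = sum(m)),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s (threshold %s), %d voxels on grid %s\n",
              x$origin, format(x$threshold), x$n_voxels,
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

check_aligned <- function(image, mask) {
  di <- dim(image$data); dm <- dim(mask$mask)
  if (!identical(di, dm)) {
    stop(sprintf("grid mismatch: image %s vs mask %s",
                 paste(di, collapse = "x"), paste(dm, collapse = "x")))
  }
  if (max(abs(image$spacing - mask$spacing)) > 1e-6) {
    stop(sprintf("spacing mismatch: image %s vs mask %s mm",
                 paste(signif(image$spacing, 6), collapse = "x"),
                 paste(signif(mask$spacing, 6), collapse = "x")))
  }
  invisible(TRUE)
}

#' Read / write PET volumes and masks as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that preserve voxel spacing and enforce
#' the package's contracts: volumes are 3D scalars, masks are binary.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param profile scanner profile label to attach on read.
#' @return `read_pet_volume` returns a [pet_volume()]; `read_voi_mask`
#'   returns a [voi_mask()].
#' @export
read_pet_volume <- function(path, profile = "unknown") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) {
    stop(sprintf("expected a 3D volume, got %d dimensions", length(dim(arr))))
  }
  pix <- RNifti::pixdim(img)[1:3]
  pet_volume(arr, pix, profile)
}

#' @rdname read_pet_volume
#' @param volume a [pet_volume()] to write.
#' @export
write_pet_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_pet_volume
#' @param origin,threshold metadata attached to the mask on read.
#' @export
read_voi_mask <- function(path, origin = "mask", threshold = NA_real_) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) {
    stop(sprintf("expected a 3D mask, got %d dimensions", length(dim(arr))))
  }
  if (!all(unique(as.vector(arr)) %in% c(0, 1))) {
    stop("mask file contains values other than 0/1")
  }
  voi_mask(arr, origin, threshold, RNifti::pixdim(img)[1:3])
}

#' @rdname read_pet_volume
#' @param mask a [voi_mask()] to write.
#' @export
write_voi_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
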