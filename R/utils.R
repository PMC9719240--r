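# Machine epsilon used inside logarithms, matching the numpy convention
# np.spacing(1) used by common radiomics implementations.
.eps <- 2.220446049250313e-16

#' Half-space neighbourhood offsets for a given 3D connectivity
#'
#' Returns the unique direction offsets (one per antiparallel pair) used for
#' co-occurrence and run-length computations: 13 offsets for 26-connectivity,
#' 3 for 6-connectivity.
#'
#' @param connectivity 6 or 26.
#' @return Integer matrix with one offset per row (columns dx, dy, dz).
#' @keywords internal
conn_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  if (connectivity == 6) {
    g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  } else if (connectivity != 26) {
    stop("connectivity must be 6 or 26")
  }
  # keep one representative per antiparallel pair (lexicographically positive)
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

# All offsets (both directions) of a 26-neighbourhood.
full_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Label connected components of a 3D mask
#'
#' 26-connected (default) component labelling, optionally refined so that two
#' neighbouring voxels are connected only when they share the same value in
#' `values` (used for gray-level size-zone computation).
#'
#' @param mask logical 3D array.
#' @param values optional array of the same shape; when given, edges join
#'   equal-valued neighbours only.
#' @param connectivity 6 or 26.
#' @return integer array of component labels (0 outside the mask).
#' @keywords internal
label_components <- function(mask, values = NULL, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  n <- length(idx)
  if (n == 0L) return(lab)
  vox_id <- array(0L, d)
  vox_id[idx] <- seq_len(n)
  coord <- arrayInd(idx, d)
  offs <- conn_offsets(connectivity)
  from <- vector("list", nrow(offs))
  to <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb1 <- coord[, 1] + o[1]; nb2 <- coord[, 2] + o[2]; nb3 <- coord[, 3] + o[3]
    ok <- nb1 >= 1L & nb1 <= d[1] & nb2 >= 1L & nb2 <= d[2] & nb3 >= 1L & nb3 <= d[3]
    if (!any(ok)) next
    nb_lin <- nb1[ok] + (nb2[ok] - 1L) * d[1] + (nb3[ok] - 1L) * d[1] * d[2]
    nbid <- vox_id[nb_lin]
    sel <- nbid > 0L
    if (!is.null(values)) {
      eq <- values[idx[ok]] == values[nb_lin]
      eq[is.na(eq)] <- FALSE
      sel <- sel & eq
    }
    if (!any(sel)) next
    from[[r]] <- seq_len(n)[ok][sel]
    to[[r]] <- nbid[sel]
  }
  from <- unlist(from); to <- unlist(to)
  if (is.null(from) || length(from) == 0L) {
    lab[idx] <- seq_len(n)
    return(lab)
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# 1D Gaussian kernel sampled at voxel centres, truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve along one axis with edge replication; implemented as a sum of
# clamped-index shifted copies, which is fast for short kernels.
convolve_axis <- function(arr, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(arr * kernel)
  d <- dim(arr)
  r <- (nk - 1L) %/% 2L
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_len(nk)) {
    o <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    shifted <- switch(axis,
      arr[idx, , , drop = FALSE],
      arr[, idx, , drop = FALSE],
      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm full width at half maximum of the Gaussian, in mm
#'   (scalar, isotropic in physical space).
#' @param spacing voxel spacing in mm (length 3).
#' @return smoothed array of the same shape.
#' @keywords internal
smooth_gaussian <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_mm / spacing[ax]), ax)
  }
  arr
}

# Zero-mean, unit-variance Gaussian random field with approximately the
# requested correlation length, built by Gaussian-filtering white noise.
# Consumes the current RNG stream.
gaussian_random_field <- function(dim, spacing, corr_length_mm) {
  w <- array(stats::rnorm(prod(dim)), dim)
  if (corr_length_mm > 0) {
    for (ax in 1:3) {
      w <- convolve_axis(w, gaussian_kernel_1d(corr_length_mm / spacing[ax]), ax)
    }
  }
  s <- stats::sd(as.vector(w))
  if (s == 0) return(array(0, dim))
  (w - mean(w)) / s
}

#' Morphological dilation of a binary mask by a physical radius
#'
#' FFT-based convolution with a spherical structuring element whose radius is
#' given in mm, thresholded at half a voxel's contribution.
#'
#' @param mask logical 3D array.
#' @param radius_mm dilation radius in mm.
#' @param spacing voxel spacing in mm.
#' @return logical array of the same shape.
#' @keywords internal
next_smooth <- function(n) {
  # smallest 5-smooth integer >= n (keeps the mixed-radix FFT fast)
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

dilate_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  if (!any(mask)) return(mask)
  d <- dim(mask)
  rv <- as.integer(ceiling(radius_mm / spacing))
  # work on the mask bounding box expanded by the dilation radius
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  lo <- pmax(bb[1, ] - rv, 1L)
  hi <- pmin(bb[2, ] + rv, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sd_ <- dim(sub)
  kd <- 2L * rv + 1L
  ax <- lapply(1:3, function(i) ((-rv[i]):rv[i]) * spacing[i])
  kr <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  kernel <- array(as.numeric(kr <= radius_mm^2), kd)
  pd <- vapply(sd_ + kd - 1L, next_smooth, numeric(1))
  pm <- array(0, pd); pk <- array(0, pd)
  pm[seq_len(sd_[1]), seq_len(sd_[2]), seq_len(sd_[3])] <- as.numeric(sub)
  pk[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  conv <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) / prod(pd)
  sub_out <- conv[rv[1] + seq_len(sd_[1]), rv[2] + seq_len(sd_[2]),
                  rv[3] + seq_len(sd_[3])] > 0.5
  out <- array(FALSE, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub_out
  out
}

# Derive a child seed from a parent seed and a stage tag, staying inside the
# 32-bit integer range so the value is portable as an R integer.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}
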