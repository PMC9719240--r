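# Gray-level texture matrix construction.
#
# All builders operate on an integer gray-level array defined on a binary
# mask. Co-occurrence and run-length matrices are computed per direction
# over the 13 unique 3D offsets at Chebyshev distance 1; size zones use
# 26-connectivity; neighbourhood statistics (NGTDM, GLDM) use the full
# 26-neighbourhood. Matrices are stored as raw counts (the GLCM per-angle
# slices already symmetrized); normalization happens in the feature
# formulas, except for the merged GLCM which is normalized to sum 1.

# Crop mask + levels to the mask bounding box (with no padding).
crop_to_mask <- function(levels, mask) {
  stopifnot(identical(dim(levels), dim(mask)))
  idx <- which(mask)
  if (length(idx) == 0L) stop("crop_to_mask: empty mask")
  co <- arrayInd(idx, dim(mask))
  rng <- apply(co, 2, range)
  sl <- lapply(1:3, function(i) rng[1, i]:rng[2, i])
  list(levels = levels[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
       mask = mask[sl[[1]], sl[[2]], sl[[3]], drop = FALSE])
}

# Shift a 3D array by an integer offset, filling vacated entries with `fill`.
shift_array <- function(arr, o, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    if (o[i] >= 0) {
      if (o[i] >= d[i]) return(out)
      src[[i]] <- 1:(d[i] - o[i]); dst[[i]] <- (1 + o[i]):d[i]
    } else {
      if (-o[i] >= d[i]) return(out)
      src[[i]] <- (1 - o[i]):d[i]; dst[[i]] <- 1:(d[i] + o[i])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Compute all five gray-level texture matrices for a discretized VOI
#'
#' @param levels integer 3D array of gray levels, defined at mask voxels.
#' @param mask logical 3D array (nonempty).
#' @param gldm_alpha dependence tolerance: a neighbour is dependent when its
#'   absolute level difference is `<= gldm_alpha` (default 0).
#' @return An object of class `texture_matrices`: `level_values` (sorted
#'   distinct gray levels present), `glcm_angles` (levels x levels x 13
#'   symmetrized counts per direction), `glcm` (direction-merged, normalized
#'   to sum 1), `glrlm_angles` (levels x max-run-length x 13 counts),
#'   `glrlm` (merged counts), `glszm` (levels x max-zone-size counts),
#'   `ngtdm` (per-level `n`, `s`, `p`), `gldm` (levels x dependence-size
#'   counts), and `n_voxels`.
#' @export
compute_texture_matrices <- function(levels, mask, gldm_alpha = 0) {
  cr <- crop_to_mask(levels, mask)
  lev <- cr$levels; msk <- cr$mask
  d <- dim(msk)
  idx <- which(msk)
  np <- length(idx)
  lv <- sort(unique(as.vector(lev[idx])))
  ng <- length(lv)
  li_arr <- array(0L, d)  # 1..Ng compact index, 0 outside mask
  li_arr[idx] <- match(lev[idx], lv)
  offs <- conn_offsets(26)
  na <- nrow(offs)

  ## GLCM per angle (symmetrized counts)
  glcm_angles <- array(0, c(ng, ng, na))
  for (a in seq_len(na)) {
    nb <- shift_array(li_arr, -offs[a, ], fill = 0L)  # value at voxel + offset
    cur <- li_arr[idx]; nbv <- nb[idx]
    ok <- nbv > 0L
    if (any(ok)) {
      cnt <- tabulate((cur[ok] - 1L) * ng + nbv[ok], nbins = ng * ng)
      m <- matrix(cnt, ng, ng, byrow = TRUE)  # row = current level, col = neighbour
      glcm_angles[, , a] <- m + t(m)
    }
  }
  glcm_merged <- apply(glcm_angles, c(1, 2), sum)
  if (sum(glcm_merged) > 0) glcm_merged <- glcm_merged / sum(glcm_merged)

  ## GLRLM per angle
  run_counts <- vector("list", na)
  maxlen <- 1L
  co <- arrayInd(idx, d)
  lin_of <- function(c1, c2, c3) c1 + (c2 - 1L) * d[1] + (c3 - 1L) * d[1] * d[2]
  inb <- function(c1, c2, c3) c1 >= 1L & c1 <= d[1] & c2 >= 1L & c2 <= d[2] &
    c3 >= 1L & c3 <= d[3]
  for (a in seq_len(na)) {
    o <- offs[a, ]
    p1 <- co[, 1] - o[1]; p2 <- co[, 2] - o[2]; p3 <- co[, 3] - o[3]
    okp <- inb(p1, p2, p3)
    prev_li <- integer(np)
    prev_li[okp] <- li_arr[lin_of(p1[okp], p2[okp], p3[okp])]
    is_start <- !(okp & prev_li == li_arr[idx])
    s1 <- co[is_start, 1]; s2 <- co[is_start, 2]; s3 <- co[is_start, 3]
    rl <- rep(1L, length(s1))
    rlev <- li_arr[lin_of(s1, s2, s3)]
    act <- seq_along(s1)
    c1 <- s1; c2 <- s2; c3 <- s3
    while (length(act) > 0) {
      c1[act] <- c1[act] + o[1]; c2[act] <- c2[act] + o[2]; c3[act] <- c3[act] + o[3]
      okn <- inb(c1[act], c2[act], c3[act])
      nxt <- integer(length(act))
      nxt[okn] <- li_arr[lin_of(c1[act][okn], c2[act][okn], c3[act][okn])]
      cont <- okn & nxt == rlev[act]
      rl[act[cont]] <- rl[act[cont]] + 1L
      act <- act[cont]
    }
    maxlen <- max(maxlen, rl)
    run_counts[[a]] <- list(lev = rlev, len = rl)
  }
  glrlm_angles <- array(0, c(ng, maxlen, na))
  for (a in seq_len(na)) {
    rc <- run_counts[[a]]
    cnt <- tabulate((rc$lev - 1L) * maxlen + rc$len, nbins = ng * maxlen)
    glrlm_angles[, , a] <- matrix(cnt, ng, maxlen, byrow = TRUE)
  }
  glrlm_merged <- apply(glrlm_angles, c(1, 2), sum)

  ## GLSZM (26-connected equal-level zones)
  zl <- label_components(msk, values = lev, connectivity = 26)
  memb <- zl[idx]
  nz <- max(memb)
  zsize <- tabulate(memb, nbins = nz)
  zlev <- integer(nz)
  zlev[memb] <- li_arr[idx]  # last write per zone; all equal within a zone
  smax <- max(zsize)
  glszm <- matrix(tabulate((zlev - 1L) * smax + zsize, nbins = ng * smax),
                  ng, smax, byrow = TRUE)

  ## NGTDM (average over valid 26-neighbours)
  lev0 <- array(0, d); lev0[idx] <- as.numeric(lev[idx])
  mnum <- array(0, d); mnum[idx] <- 1
  nb_sum <- array(0, d); nb_cnt <- array(0, d)
  for (o in asplit(full_offsets_26(), 1)) {
    nb_sum <- nb_sum + shift_array(lev0, -as.integer(o))
    nb_cnt <- nb_cnt + shift_array(mnum, -as.integer(o))
  }
  has_nb <- msk & nb_cnt > 0
  avals <- nb_sum[has_nb] / nb_cnt[has_nb]
  lvals <- as.numeric(lev[has_nb])
  lidx <- match(lev[has_nb], lv)
  n_i <- tabulate(lidx, nbins = ng)
  s_full <- numeric(ng)
  if (length(lidx) > 0) {
    tmp <- rowsum(abs(lvals - avals), lidx)
    s_full[as.integer(rownames(tmp))] <- tmp[, 1]
  }
  nvp <- sum(n_i)
  ngtdm <- data.frame(level = lv, n = n_i, s = s_full,
                      p = if (nvp > 0) n_i / nvp else rep(0, ng))

  ## GLDM (dependence on the 26-neighbourhood)
  dep <- array(0L, d)
  for (o in asplit(full_offsets_26(), 1)) {
    nb_lev <- shift_array(lev0, -as.integer(o))
    nb_in <- shift_array(mnum, -as.integer(o))
    dep <- dep + as.integer(nb_in > 0 & abs(nb_lev - lev0) <= gldm_alpha)
  }
  dsize <- dep[idx] + 1L  # the centre voxel always depends on itself
  dmax <- max(dsize)
  gldm <- matrix(tabulate((li_arr[idx] - 1L) * dmax + dsize, nbins = ng * dmax),
                 ng, dmax, byrow = TRUE)

  structure(list(level_values = lv, n_voxels = np,
                 glcm_angles = glcm_angles, glcm = glcm_merged,
                 glrlm_angles = glrlm_angles, glrlm = glrlm_merged,
                 glszm = glszm, ngtdm = ngtdm, gldm = gldm),
            class = "texture_matrices")
}
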