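# Shape (morphology) features of a binary VOI.
#
# Axis-based features come from the eigenvalues of the covariance of the
# physical voxel-centre coordinates. Mesh-based features (surface area,
# mesh volume and derived quantities) use a surface mesh extracted by
# marching tetrahedra on the zero-padded mask (Kuhn 6-tetrahedron cube
# subdivision, iso-level 0.5, vertices at edge midpoints); the subdivision
# is face-compatible across cubes, so the mesh is closed and consistently
# orientable.

# Corner offsets of a unit cube, binary order (x fastest).
.cube_corners <- as.matrix(expand.grid(cx = 0:1, cy = 0:1, cz = 0:1))

# Kuhn subdivision: six tetrahedra sharing the main diagonal c(0,0,0)-c(1,1,1).
# Rows index into .cube_corners (1-based binary order: 1=000, 2=100, 3=010,
# 4=110, 5=001, 6=101, 7=011, 8=111).
.cube_tets <- rbind(
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

# Triangles cut by the iso-surface in a tetrahedron whose corners have the
# given inside pattern; each triangle is three edges (inside, outside) whose
# midpoints are the vertices. Derived from first principles: one inside
# corner gives one triangle, two give a quad split into two triangles.
tet_case_triangles <- function(bits) {
  ins <- which(bits); outs <- which(!bits)
  if (length(ins) %in% c(0L, 4L)) return(list())
  if (length(ins) == 1L) {
    return(list(list(c(ins, outs[1]), c(ins, outs[2]), c(ins, outs[3]))))
  }
  if (length(ins) == 3L) {
    return(list(list(c(ins[1], outs), c(ins[2], outs), c(ins[3], outs))))
  }
  e11 <- c(ins[1], outs[1]); e12 <- c(ins[1], outs[2])
  e21 <- c(ins[2], outs[1]); e22 <- c(ins[2], outs[2])
  list(list(e11, e12, e22), list(e11, e22, e21))
}

.tet_cases <- lapply(0:15, function(m) tet_case_triangles(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0))

#' Extract a closed surface mesh from a binary mask
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @return List with `v1`, `v2`, `v3` (n_triangles x 3 matrices of vertex
#'   coordinates in mm, consistently oriented with outward normals).
#' @keywords internal
mask_mesh <- function(mask, spacing) {
  d <- dim(mask)
  pd <- d + 2L
  p <- array(FALSE, pd)
  p[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask
  # cube corner values: cube (i,j,k) spans voxels (i..i+1, j..j+1, k..k+1)
  nc <- pd - 1L
  cv <- matrix(FALSE, prod(nc), 8)
  for (c8 in 1:8) {
    o <- .cube_corners[c8, ]
    cv[, c8] <- as.vector(p[o[1] + seq_len(nc[1]), o[2] + seq_len(nc[2]),
                            o[3] + seq_len(nc[3])])
  }
  s <- rowSums(cv)
  active <- which(s > 0 & s < 8)
  if (length(active) == 0L) {
    return(list(v1 = matrix(0, 0, 3), v2 = matrix(0, 0, 3), v3 = matrix(0, 0, 3)))
  }
  cv <- cv[active, , drop = FALSE]
  base <- arrayInd(active, nc)  # cube origin = padded voxel index of corner 000
  tri1 <- list(); tri2 <- list(); tri3 <- list(); ref <- list()
  k <- 0L
  for (t in seq_len(nrow(.cube_tets))) {
    tc <- .cube_tets[t, ]
    tv <- cv[, tc, drop = FALSE]
    caseid <- tv[, 1] + 2L * tv[, 2] + 4L * tv[, 3] + 8L * tv[, 4]
    for (cs in 1:15) {
      tris <- .tet_cases[[cs + 1L]]
      if (length(tris) == 0L) next
      sel <- which(caseid == cs)
      if (length(sel) == 0L) next
      b <- base[sel, , drop = FALSE]
      # physical coords of the four tet corners for the selected cubes
      corner_xyz <- lapply(1:4, function(ci) {
        off <- .cube_corners[tc[ci], ]
        cbind((b[, 1] - 1 + off[1]) * spacing[1],
              (b[, 2] - 1 + off[2]) * spacing[2],
              (b[, 3] - 1 + off[3]) * spacing[3])
      })
      bits <- bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0
      insref <- Reduce(`+`, corner_xyz[which(bits)]) / sum(bits)
      for (tr in tris) {
        mid <- lapply(tr, function(e) (corner_xyz[[e[1]]] + corner_xyz[[e[2]]]) / 2)
        # orient so the normal points away from the inside corners
        nrm <- cross_rows(mid[[2]] - mid[[1]], mid[[3]] - mid[[1]])
        cen <- (mid[[1]] + mid[[2]] + mid[[3]]) / 3
        flip <- rowSums(nrm * (cen - insref)) < 0
        a <- mid[[2]]; b2 <- mid[[3]]
        a[flip, ] <- mid[[3]][flip, ]; b2[flip, ] <- mid[[2]][flip, ]
        k <- k + 1L
        tri1[[k]] <- mid[[1]]; tri2[[k]] <- a; tri3[[k]] <- b2
      }
    }
  }
  list(v1 = do.call(rbind, tri1), v2 = do.call(rbind, tri2),
       v3 = do.call(rbind, tri3))
}

# Iso-surface vertices on cube edges: midpoints of axis-aligned voxel pairs
# whose mask values differ (the canonical marching-cubes vertex positions
# for binary data; excludes the extra face-/body-diagonal vertices the
# tetrahedral tessellation introduces). Used for the diameter features.
iso_edge_vertices <- function(mask, spacing) {
  d <- dim(mask)
  pd <- d + 2L
  p <- array(FALSE, pd)
  p[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask
  pts <- list()
  for (ax in 1:3) {
    n <- pd[ax]
    hi <- switch(ax, p[-1, , , drop = FALSE], p[, -1, , drop = FALSE],
                 p[, , -1, drop = FALSE])
    lo <- switch(ax, p[-n, , , drop = FALSE], p[, -n, , drop = FALSE],
                 p[, , -n, drop = FALSE])
    cross <- which(hi != lo)
    if (length(cross) == 0L) next
    co <- arrayInd(cross, dim(lo))
    co <- co - 1  # coordinate of the lower voxel in 0-based padded units
    co[, ax] <- co[, ax] + 0.5
    pts[[ax]] <- co
  }
  v <- do.call(rbind, pts)
  sweep(v, 2, spacing, "*")
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Largest pairwise distance among points (rows). Exact up to `exact_limit`
# points; beyond that, reduces to directional-extreme candidates first
# (deterministic Fibonacci-sphere directions), which is exact for practical
# convex-ish vertex clouds and a tight lower bound otherwise.
max_pairwise_distance <- function(pts, exact_limit = 1500L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  dmax2 <- function(p) {
    g <- tcrossprod(p)
    sq <- diag(g)
    max(outer(sq, sq, "+") - 2 * g)
  }
  if (n <= exact_limit) return(sqrt(max(0, dmax2(pts))))
  nd <- 250L
  i <- seq_len(nd)
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - (2 * i - 1) / nd
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(theta), r * sin(theta), z)
  if (ncol(pts) == 2L) dirs <- unique(rbind(dirs[, 1:2], c(1, 0), c(0, 1)))
  proj <- pts %*% t(dirs)
  cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  sqrt(max(0, dmax2(pts[cand, , drop = FALSE])))
}

#' Shape features of a binary VOI
#'
#' The 14 standard 3D morphology features: mesh volume, voxel volume,
#' surface area, surface-to-volume ratio, sphericity, the four maximum
#' diameters, the three principal axis lengths (4 sqrt(eigenvalue) of the
#' physical coordinate covariance), elongation and flatness.
#'
#' Degenerate conventions: a single-voxel mask has axis lengths 0 and
#' elongation and flatness 1.
#'
#' @param mask logical 3D array (nonempty).
#' @param spacing voxel spacing in mm.
#' @return Named numeric vector of 14 features, names prefixed `SH_`.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask)
  np <- length(idx)
  if (np == 0L) stop("shape_features: empty mask")
  co <- arrayInd(idx, dim(mask))
  xyz <- cbind(co[, 1] * spacing[1], co[, 2] * spacing[2], co[, 3] * spacing[3])
  if (np >= 2L) {
    ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  mesh <- mask_mesh(mask, spacing)
  e1 <- mesh$v2 - mesh$v1; e2 <- mesh$v3 - mesh$v1
  area <- sum(sqrt(rowSums(cross_rows(e1, e2)^2))) / 2
  vol <- abs(sum(rowSums(mesh$v1 * cross_rows(mesh$v2, mesh$v3)))) / 6
  verts <- unique(round(iso_edge_vertices(mask, spacing), 9))
  d3 <- max_pairwise_distance(verts)
  d_slice <- max_pairwise_distance(unique(verts[, c(1, 2), drop = FALSE]))   # axial
  d_col <- max_pairwise_distance(unique(verts[, c(1, 3), drop = FALSE]))     # coronal
  d_row <- max_pairwise_distance(unique(verts[, c(2, 3), drop = FALSE]))     # sagittal

  out <- c(
    MeshVolume = vol,
    VoxelVolume = np * prod(spacing),
    SurfaceArea = area,
    SurfaceVolumeRatio = if (vol > 0) area / vol else 0,
    Sphericity = if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else 1,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = elong,
    Flatness = flat)
  names(out) <- paste0("SH_", names(out))
  out
}
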