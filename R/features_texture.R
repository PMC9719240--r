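# Texture feature formulas over the gray-level matrices.
#
# GLCM and GLRLM features are computed per direction and averaged over the
# 13 directions (feature-wise mean, the convention of the reference
# extraction software); set aggregation = "merged" to compute them on the
# direction-summed matrices instead. Gray-level weights use the actual
# discretized level values, not re-indexed ranks.

# Geometry shared by all 13 directional GLCMs of one VOI: level grids,
# absolute-difference and sum index maps (used to marginalize p by rowsum).
glcm_geometry <- function(lv) {
  ng <- length(lv)
  I <- matrix(lv, ng, ng)
  J <- t(I)
  dif <- abs(I - J)
  dvals <- sort(unique(as.vector(dif)))
  s <- I + J
  svals <- sort(unique(as.vector(s)))
  list(ng = ng, I = I, J = J, dif = dif, dvals = dvals,
       dif_idx = match(as.vector(dif), dvals), svals = svals,
       s_idx = match(as.vector(s), svals))
}

glcm_features_single <- function(P, lv, geom = glcm_geometry(lv)) {
  tot <- sum(P)
  nms <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares")
  if (tot == 0) {
    out <- rep(NA_real_, length(nms)); names(out) <- nms
    return(out)
  }
  p <- P / tot
  ng <- geom$ng
  I <- geom$I
  J <- geom$J
  px <- rowSums(p)  # == colSums by symmetry
  mux <- sum(lv * px)
  sigx <- sqrt(sum((lv - mux)^2 * px))
  dif <- geom$dif
  dvals <- geom$dvals
  pd <- numeric(length(dvals))
  agg <- rowsum(as.vector(p), geom$dif_idx)
  pd[as.integer(rownames(agg))] <- agg[, 1]
  svals <- geom$svals
  ps <- numeric(length(svals))
  agg <- rowsum(as.vector(p), geom$s_idx)
  ps[as.integer(rownames(agg))] <- agg[, 1]
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  pxpy <- outer(px, px)
  hxy <- -sum(p * log2(p + .eps))
  hxy1 <- -sum(p * log2(pxpy + .eps))
  hxy2 <- -sum(pxpy * log2(pxpy + .eps))
  da <- sum(dvals * pd)
  present <- px > 0
  mcc <- 1
  if (sum(present) > 1) {
    pp <- p[present, present, drop = FALSE]
    pxp <- px[present]
    Q <- matrix(0, nrow(pp), ncol(pp))
    for (kk in seq_len(ncol(pp))) {
      Q <- Q + outer(pp[, kk] / pxp, pp[, kk] / pxp[kk])
    }
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, evq[2]))
  }
  corr <- if (sigx > 0) (sum(I * J * p) - mux^2) / sigx^2 else 1
  offd <- dif > 0
  c(Autocorrelation = sum(I * J * p),
    ClusterProminence = sum((I + J - 2 * mux)^4 * p),
    ClusterShade = sum((I + J - 2 * mux)^3 * p),
    ClusterTendency = sum((I + J - 2 * mux)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0] + .eps)),
    DifferenceVariance = sum((dvals - da)^2 * pd),
    Id = sum(p / (1 + dif)),
    Idm = sum(p / (1 + dif^2)),
    Idmn = sum(p / (1 + (dif / ng)^2)),
    Idn = sum(p / (1 + dif / ng)),
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0,
    InverseVariance = if (any(offd)) sum(p[offd] / dif[offd]^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(svals * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0] + .eps)),
    SumSquares = sum((I - mux)^2 * p))
}

#' Gray-level co-occurrence features
#'
#' @param tm a [compute_texture_matrices()] result.
#' @param aggregation `"mean"` (per-direction features averaged, default) or
#'   `"merged"` (features of the direction-summed matrix).
#' @return Named numeric vector of 24 features, prefixed `GLCM_`.
#' @export
glcm_features <- function(tm, aggregation = c("mean", "merged")) {
  aggregation <- match.arg(aggregation)
  lv <- tm$level_values
  if (aggregation == "merged") {
    out <- glcm_features_single(tm$glcm, lv)
  } else {
    na_ <- dim(tm$glcm_angles)[3]
    ng_ <- dim(tm$glcm_angles)[1]
    geom <- glcm_geometry(lv)
    per <- vapply(seq_len(na_), function(a) {
      sl <- tm$glcm_angles[, , a, drop = FALSE]
      dim(sl) <- c(ng_, ng_)
      glcm_features_single(sl, lv, geom)
    }, numeric(24))
    out <- rowMeans(per, na.rm = TRUE)
  }
  # single-voxel / no-pair VOIs: fall back to defined defaults
  defaults <- c(Autocorrelation = if (length(lv)) lv[1]^2 else 0,
                ClusterProminence = 0, ClusterShade = 0, ClusterTendency = 0,
                Contrast = 0, Correlation = 1, DifferenceAverage = 0,
                DifferenceEntropy = 0, DifferenceVariance = 0, Id = 1, Idm = 1,
                Idmn = 1, Idn = 1, Imc1 = 0, Imc2 = 0, InverseVariance = 0,
                JointAverage = if (length(lv)) lv[1] else 0, JointEnergy = 1,
                JointEntropy = 0, MCC = 1, MaximumProbability = 1,
                SumAverage = if (length(lv)) 2 * lv[1] else 0, SumEntropy = 0,
                SumSquares = 0)
  nan <- !is.finite(out)
  out[nan] <- defaults[names(out)[nan]]
  names(out) <- paste0("GLCM_", names(out))
  out
}

rlm_features_single <- function(P, lv, np) {
  nr <- sum(P)
  iv <- lv
  jv <- seq_len(ncol(P))
  if (nr == 0) return(rep(NA_real_, 16))
  p <- P / nr
  ri <- rowSums(P); rj <- colSums(P)
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum(iv * pi_); muj <- sum(jv * pj)
  c(GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum((iv - mui)^2 * pi_),
    HighGrayLevelRunEmphasis = sum(iv^2 * pi_),
    LongRunEmphasis = sum(jv^2 * pj),
    LongRunHighGrayLevelEmphasis = sum(outer(iv^2, jv^2) * p),
    LongRunLowGrayLevelEmphasis = sum(outer(1 / iv^2, jv^2) * p),
    LowGrayLevelRunEmphasis = sum(pi_ / iv^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0] + .eps)),
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum((jv - muj)^2 * pj),
    ShortRunEmphasis = sum(pj / jv^2),
    ShortRunHighGrayLevelEmphasis = sum(outer(iv^2, 1 / jv^2) * p),
    ShortRunLowGrayLevelEmphasis = sum(outer(1 / iv^2, 1 / jv^2) * p))
}

#' Gray-level run-length features
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features, prefixed `GLRLM_`.
#' @export
glrlm_features <- function(tm, aggregation = c("mean", "merged")) {
  aggregation <- match.arg(aggregation)
  lv <- tm$level_values
  if (aggregation == "merged") {
    out <- rlm_features_single(tm$glrlm, lv, tm$n_voxels * dim(tm$glrlm_angles)[3])
    names(out) <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                    "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                    "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                    "RunEntropy", "RunLengthNonUniformity",
                    "RunLengthNonUniformityNormalized", "RunPercentage",
                    "RunVariance", "ShortRunEmphasis",
                    "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
  } else {
    dd <- dim(tm$glrlm_angles)
    per <- vapply(seq_len(dd[3]), function(a) {
      sl <- tm$glrlm_angles[, , a, drop = FALSE]
      dim(sl) <- dd[1:2]
      rlm_features_single(sl, lv, tm$n_voxels)
    }, numeric(16))
    rownames(per) <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                       "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                       "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                       "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                       "RunEntropy", "RunLengthNonUniformity",
                       "RunLengthNonUniformityNormalized", "RunPercentage",
                       "RunVariance", "ShortRunEmphasis",
                       "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
    out <- rowMeans(per, na.rm = TRUE)
  }
  out[!is.finite(out)] <- 0
  names(out) <- paste0("GLRLM_", names(out))
  out
}

#' Gray-level size-zone features
#'
#' @param tm a [compute_texture_matrices()] result.
#' @return Named numeric vector of 16 features, prefixed `GLSZM_`.
#' @export
glszm_features <- function(tm) {
  P <- tm$glszm
  lv <- tm$level_values
  nz <- sum(P)
  np <- tm$n_voxels
  jv <- seq_len(ncol(P))
  # the size-zone matrix is wide (columns up to the largest zone) but very
  # sparse; cross-moment features iterate its nonzero entries only
  nzi <- which(P != 0, arr.ind = TRUE)
  pv <- P[nzi] / nz
  ivz <- lv[nzi[, 1]]; jvz <- jv[nzi[, 2]]
  pi_ <- numeric(length(lv)); pj <- numeric(length(jv))
  agg <- rowsum(pv, nzi[, 1]); pi_[as.integer(rownames(agg))] <- agg[, 1]
  agg <- rowsum(pv, nzi[, 2]); pj[as.integer(rownames(agg))] <- agg[, 1]
  si <- pi_ * nz; sj <- pj * nz
  mui <- sum(lv * pi_); muj <- sum(jv * pj)
  out <- c(
    GrayLevelNonUniformity = sum(si^2) / nz,
    GrayLevelNonUniformityNormalized = sum(si^2) / nz^2,
    GrayLevelVariance = sum((lv - mui)^2 * pi_),
    HighGrayLevelZoneEmphasis = sum(lv^2 * pi_),
    LargeAreaEmphasis = sum(jv^2 * pj),
    LargeAreaHighGrayLevelEmphasis = sum(ivz^2 * jvz^2 * pv),
    LargeAreaLowGrayLevelEmphasis = sum(jvz^2 * pv / ivz^2),
    LowGrayLevelZoneEmphasis = sum(pi_ / lv^2),
    SizeZoneNonUniformity = sum(sj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sj^2) / nz^2,
    SmallAreaEmphasis = sum(pj / jv^2),
    SmallAreaHighGrayLevelEmphasis = sum(ivz^2 * pv / jvz^2),
    SmallAreaLowGrayLevelEmphasis = sum(pv / (ivz^2 * jvz^2)),
    ZoneEntropy = -sum(pv * log2(pv + .eps)),
    ZonePercentage = nz / np,
    ZoneVariance = sum((jv - muj)^2 * pj))
  names(out) <- paste0("GLSZM_", names(out))
  out
}

#' Neighbouring gray-tone difference features
#'
#' @param tm a [compute_texture_matrices()] result.
#' @return Named numeric vector of 5 features, prefixed `NGTDM_`.
#' @export
ngtdm_features <- function(tm) {
  m <- tm$ngtdm
  keep <- m$p > 0
  iv <- m$level[keep]; pv <- m$p[keep]; sv <- m$s[keep]
  ngp <- sum(keep)
  nvp <- sum(m$n)
  ps_sum <- sum(pv * sv)
  coarseness <- if (ps_sum > 0) 1 / ps_sum else 1e6
  contrast <- if (ngp > 1 && nvp > 0) {
    sum(outer(pv, pv) * outer(iv, iv, function(a, b) (a - b)^2)) /
      (ngp * (ngp - 1)) * sum(sv) / nvp
  } else 0
  ipi <- iv * pv
  busy_den <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (busy_den > 0) ps_sum / busy_den else 0
  dmat <- abs(outer(iv, iv, "-"))
  psum <- outer(pv, pv, "+")
  smat <- outer(pv * sv, pv * sv, "+")
  complexity <- if (nvp > 0) sum(dmat * smat / psum) / nvp else 0
  s_sum <- sum(sv)
  strength <- if (s_sum > 0) sum(psum * dmat^2) / s_sum else 0
  out <- c(Busyness = busyness, Coarseness = coarseness,
           Complexity = complexity, Contrast = contrast, Strength = strength)
  names(out) <- paste0("NGTDM_", names(out))
  out
}

#' Gray-level dependence features
#'
#' @param tm a [compute_texture_matrices()] result.
#' @return Named numeric vector of 14 features, prefixed `GLDM_`.
#' @export
gldm_features <- function(tm) {
  P <- tm$gldm
  lv <- tm$level_values
  nz <- sum(P)
  jv <- seq_len(ncol(P))
  p <- P / nz
  pi_ <- rowSums(p); pj <- colSums(p)
  si <- rowSums(P); sj <- colSums(P)
  mui <- sum(lv * pi_); muj <- sum(jv * pj)
  out <- c(
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0] + .eps)),
    DependenceNonUniformity = sum(sj^2) / nz,
    DependenceNonUniformityNormalized = sum(sj^2) / nz^2,
    DependenceVariance = sum((jv - muj)^2 * pj),
    GrayLevelNonUniformity = sum(si^2) / nz,
    GrayLevelVariance = sum((lv - mui)^2 * pi_),
    HighGrayLevelEmphasis = sum(lv^2 * pi_),
    LargeDependenceEmphasis = sum(jv^2 * pj),
    LargeDependenceHighGrayLevelEmphasis = sum(outer(lv^2, jv^2) * p),
    LargeDependenceLowGrayLevelEmphasis = sum(outer(1 / lv^2, jv^2) * p),
    LowGrayLevelEmphasis = sum(pi_ / lv^2),
    SmallDependenceEmphasis = sum(pj / jv^2),
    SmallDependenceHighGrayLevelEmphasis = sum(outer(lv^2, 1 / jv^2) * p),
    SmallDependenceLowGrayLevelEmphasis = sum(outer(1 / lv^2, 1 / jv^2) * p))
  names(out) <- paste0("GLDM_", names(out))
  out
}
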