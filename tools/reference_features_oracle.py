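#!/usr/bin/env python
"""Independent reference oracle for the 107-feature radiomics engine.

Computes the default 107-feature set (18 first-order, 14 shape, 24 GLCM,
16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) on the package's deterministic
digital phantom, using numpy/scipy/scikit-image only and sharing no code
with the R implementation. Feature definitions follow the IBSI-aligned
formulas documented by the standard radiomics extraction software
(fixed bin width 0.04, bin edges aligned to integer multiples of the
width; GLCM/GLRLM features averaged over the 13 unique 3D directions;
26-connected zones; Chebyshev-1 neighbourhoods; GLDM alpha = 0 with
dependence size = dependent neighbours + 1).

Run from the repository root:
    python tools/reference_features_oracle.py
and it rewrites inst/extdata/digital_phantom_oracle_features.csv, the
frozen expected values used by the test suite.
"""
import numpy as np
from scipy import ndimage
from skimage import measure

EPS = np.spacing(1.0)
BIN_WIDTH = 0.04

# ---------------------------------------------------------------- phantom
def phantom():
    d = (20, 18, 14)
    sp = np.array([2.0, 2.0, 2.4])
    i, j, k = np.meshgrid(np.arange(1, d[0] + 1), np.arange(1, d[1] + 1),
                          np.arange(1, d[2] + 1), indexing="ij")
    ctr = (np.array(d) + 1) / 2
    ux = (i - ctr[0]) * sp[0]
    uy = (j - ctr[1]) * sp[1]
    uz = (k - ctr[2]) * sp[2]
    r = np.sqrt((ux / 16) ** 2 + (uy / 12) ** 2 + (uz / 10) ** 2)
    mask = r <= 1
    val = (1.0 + 1.6 * np.maximum(0, 1 - r)
           + 0.30 * np.sin(1.7 * i) * np.cos(2.3 * j) * np.sin(1.1 * k)
           + 0.15 * np.cos(0.7 * i + 1.3 * j + 2.1 * k))
    return val, mask, sp


def discretize(vals, width):
    # bin edges aligned to integer multiples of the width
    return (np.floor(vals / width) - np.floor(vals.min() / width) + 1).astype(int)


# ------------------------------------------------------------- first order
def first_order(vals, lev, sp):
    n = vals.size
    mu = vals.mean()
    m2 = ((vals - mu) ** 2).mean()
    m3 = ((vals - mu) ** 3).mean()
    m4 = ((vals - mu) ** 4).mean()
    _, cnt = np.unique(lev, return_counts=True)
    p = cnt / n
    q10, q25, q50, q75, q90 = np.percentile(vals, [10, 25, 50, 75, 90])
    inner = vals[(vals >= q10) & (vals <= q90)]
    energy = (vals ** 2).sum()
    return {
        "FO_Energy": energy,
        "FO_TotalEnergy": np.prod(sp) * energy,
        "FO_Entropy": -(p * np.log2(p + EPS)).sum(),
        "FO_Minimum": vals.min(),
        "FO_Percentile10": q10,
        "FO_Percentile90": q90,
        "FO_Maximum": vals.max(),
        "FO_Mean": mu,
        "FO_Median": q50,
        "FO_InterquartileRange": q75 - q25,
        "FO_Range": vals.max() - vals.min(),
        "FO_MeanAbsoluteDeviation": np.abs(vals - mu).mean(),
        "FO_RobustMeanAbsoluteDeviation": np.abs(inner - inner.mean()).mean(),
        "FO_RootMeanSquared": np.sqrt((vals ** 2).mean()),
        "FO_Skewness": m3 / m2 ** 1.5,
        "FO_Kurtosis": m4 / m2 ** 2,
        "FO_Variance": m2,
        "FO_Uniformity": (p ** 2).sum(),
    }


# ------------------------------------------------------------------ shape
def shape(mask, sp):
    idx = np.argwhere(mask)
    xyz = (idx + 1) * sp  # physical voxel-centre coordinates
    ev = np.sort(np.linalg.eigvalsh(np.cov(xyz.T)))[::-1]
    ev = np.maximum(ev, 0)
    major, minor, least = 4 * np.sqrt(ev)
    pad = np.pad(mask.astype(float), 1)
    verts, faces, _, _ = measure.marching_cubes(pad, level=0.5)
    verts_mm = (verts - 1 + 1) * sp  # unpad (-1), convert 0-based to 1-based (+1)
    area = measure.mesh_surface_area(verts_mm, faces)
    tri = verts_mm[faces]
    vol = np.abs(np.einsum("ij,ij->i", tri[:, 0],
                           np.cross(tri[:, 1], tri[:, 2])).sum()) / 6
    def maxdist(p):
        if len(p) < 2:
            return 0.0
        d2 = ((p[:, None, :] - p[None, :, :]) ** 2).sum(-1)
        return float(np.sqrt(d2.max()))
    v = np.unique(np.round(verts_mm, 9), axis=0)
    return {
        "SH_MeshVolume": vol,
        "SH_VoxelVolume": mask.sum() * np.prod(sp),
        "SH_SurfaceArea": area,
        "SH_SurfaceVolumeRatio": area / vol,
        "SH_Sphericity": (36 * np.pi * vol ** 2) ** (1 / 3) / area,
        "SH_Maximum3DDiameter": maxdist(v),
        "SH_Maximum2DDiameterSlice": maxdist(np.unique(v[:, [0, 1]], axis=0)),
        "SH_Maximum2DDiameterColumn": maxdist(np.unique(v[:, [0, 2]], axis=0)),
        "SH_Maximum2DDiameterRow": maxdist(np.unique(v[:, [1, 2]], axis=0)),
        "SH_MajorAxisLength": major,
        "SH_MinorAxisLength": minor,
        "SH_LeastAxisLength": least,
        "SH_Elongation": np.sqrt(ev[1] / ev[0]),
        "SH_Flatness": np.sqrt(ev[2] / ev[0]),
    }


OFFSETS = [(dx, dy, dz)
           for dx in (-1, 0, 1) for dy in (-1, 0, 1) for dz in (-1, 0, 1)
           if (dz > 0) or (dz == 0 and dy > 0) or (dz == 0 and dy == 0 and dx > 0)]
ALL26 = [(dx, dy, dz)
         for dx in (-1, 0, 1) for dy in (-1, 0, 1) for dz in (-1, 0, 1)
         if (dx, dy, dz) != (0, 0, 0)]


def glcm_single(P, lv):
    p = P / P.sum()
    I = lv[:, None] * np.ones_like(p)
    J = lv[None, :] * np.ones_like(p)
    px = p.sum(1)
    mux = (lv * px).sum()
    sigx2 = ((lv - mux) ** 2 * px).sum()
    dif = np.abs(I - J)
    dvals = np.unique(dif)
    pd = np.array([p[dif == k].sum() for k in dvals])
    s = I + J
    svals = np.unique(s)
    ps = np.array([p[s == k].sum() for k in svals])
    hx = -(px[px > 0] * np.log2(px[px > 0])).sum()
    pxpy = np.outer(px, px)
    hxy = -(p * np.log2(p + EPS)).sum()
    hxy1 = -(p * np.log2(pxpy + EPS)).sum()
    hxy2 = -(pxpy * np.log2(pxpy + EPS)).sum()
    da = (dvals * pd).sum()
    ng = len(lv)
    pres = px > 0
    pp = p[np.ix_(pres, pres)]
    pxp = px[pres]
    Q = np.zeros_like(pp)
    for kk in range(pp.shape[1]):
        Q += np.outer(pp[:, kk] / pxp, pp[:, kk] / pxp[kk])
    evq = np.sort(np.real(np.linalg.eigvals(Q)))[::-1]
    mcc = np.sqrt(max(0.0, evq[1])) if len(evq) > 1 else 1.0
    offd = dif > 0
    return {
        "Autocorrelation": (I * J * p).sum(),
        "ClusterProminence": ((I + J - 2 * mux) ** 4 * p).sum(),
        "ClusterShade": ((I + J - 2 * mux) ** 3 * p).sum(),
        "ClusterTendency": ((I + J - 2 * mux) ** 2 * p).sum(),
        "Contrast": ((I - J) ** 2 * p).sum(),
        "Correlation": ((I * J * p).sum() - mux ** 2) / sigx2 if sigx2 > 0 else 1.0,
        "DifferenceAverage": da,
        "DifferenceEntropy": -(pd[pd > 0] * np.log2(pd[pd > 0] + EPS)).sum(),
        "DifferenceVariance": ((dvals - da) ** 2 * pd).sum(),
        "Id": (p / (1 + dif)).sum(),
        "Idm": (p / (1 + dif ** 2)).sum(),
        "Idmn": (p / (1 + (dif / ng) ** 2)).sum(),
        "Idn": (p / (1 + dif / ng)).sum(),
        "Imc1": (hxy - hxy1) / hx if hx > 0 else 0.0,
        "Imc2": np.sqrt(1 - np.exp(-2 * (hxy2 - hxy))) if hxy2 >= hxy else 0.0,
        "InverseVariance": (p[offd] / dif[offd] ** 2).sum(),
        "JointAverage": mux,
        "JointEnergy": (p ** 2).sum(),
        "JointEntropy": hxy,
        "MCC": mcc,
        "MaximumProbability": p.max(),
        "SumAverage": (svals * ps).sum(),
        "SumEntropy": -(ps[ps > 0] * np.log2(ps[ps > 0] + EPS)).sum(),
        "SumSquares": ((I - mux) ** 2 * p).sum(),
    }


def glcm(lev, mask, lv):
    li = {v: n for n, v in enumerate(lv)}
    d = mask.shape
    feats = []
    for o in OFFSETS:
        M = np.zeros((len(lv), len(lv)))
        for (x, y, z) in np.argwhere(mask):
            nx, ny, nz = x + o[0], y + o[1], z + o[2]
            if 0 <= nx < d[0] and 0 <= ny < d[1] and 0 <= nz < d[2] and mask[nx, ny, nz]:
                M[li[lev[x, y, z]], li[lev[nx, ny, nz]]] += 1
        M = M + M.T
        feats.append(glcm_single(M, lv.astype(float)))
    out = {}
    for k in feats[0]:
        out["GLCM_" + k] = float(np.mean([f[k] for f in feats]))
    return out


def rlm_single(P, lv, npix):
    nr = P.sum()
    p = P / nr
    iv = lv.astype(float)
    jv = np.arange(1, P.shape[1] + 1, dtype=float)
    pi = p.sum(1)
    pj = p.sum(0)
    ri = P.sum(1)
    rj = P.sum(0)
    mui = (iv * pi).sum()
    muj = (jv * pj).sum()
    return {
        "GrayLevelNonUniformity": (ri ** 2).sum() / nr,
        "GrayLevelNonUniformityNormalized": (ri ** 2).sum() / nr ** 2,
        "GrayLevelVariance": ((iv - mui) ** 2 * pi).sum(),
        "HighGrayLevelRunEmphasis": (iv ** 2 * pi).sum(),
        "LongRunEmphasis": (jv ** 2 * pj).sum(),
        "LongRunHighGrayLevelEmphasis": (np.outer(iv ** 2, jv ** 2) * p).sum(),
        "LongRunLowGrayLevelEmphasis": (np.outer(1 / iv ** 2, jv ** 2) * p).sum(),
        "LowGrayLevelRunEmphasis": (pi / iv ** 2).sum(),
        "RunEntropy": -(p[p > 0] * np.log2(p[p > 0] + EPS)).sum(),
        "RunLengthNonUniformity": (rj ** 2).sum() / nr,
        "RunLengthNonUniformityNormalized": (rj ** 2).sum() / nr ** 2,
        "RunPercentage": nr / npix,
        "RunVariance": ((jv - muj) ** 2 * pj).sum(),
        "ShortRunEmphasis": (pj / jv ** 2).sum(),
        "ShortRunHighGrayLevelEmphasis": (np.outer(iv ** 2, 1 / jv ** 2) * p).sum(),
        "ShortRunLowGrayLevelEmphasis": (np.outer(1 / iv ** 2, 1 / jv ** 2) * p).sum(),
    }


def glrlm(lev, mask, lv):
    li = {v: n for n, v in enumerate(lv)}
    d = mask.shape
    npix = int(mask.sum())
    feats = []
    for o in OFFSETS:
        runs = {}
        seen = np.zeros(d, bool)
        for (x, y, z) in np.argwhere(mask):
            px, py, pz = x - o[0], y - o[1], z - o[2]
            starts_run = not (0 <= px < d[0] and 0 <= py < d[1] and 0 <= pz < d[2]
                              and mask[px, py, pz] and lev[px, py, pz] == lev[x, y, z])
            if not starts_run:
                continue
            length = 1
            cx, cy, cz = x + o[0], y + o[1], z + o[2]
            while (0 <= cx < d[0] and 0 <= cy < d[1] and 0 <= cz < d[2]
                   and mask[cx, cy, cz] and lev[cx, cy, cz] == lev[x, y, z]):
                length += 1
                cx, cy, cz = cx + o[0], cy + o[1], cz + o[2]
            runs.setdefault((li[lev[x, y, z]], length), 0)
            runs[(li[lev[x, y, z]], length)] += 1
        maxlen = max(l for (_, l) in runs)
        P = np.zeros((len(lv), maxlen))
        for (g, l), c in runs.items():
            P[g, l - 1] = c
        feats.append(rlm_single(P, lv, npix))
    out = {}
    for k in feats[0]:
        out["GLRLM_" + k] = float(np.mean([f[k] for f in feats]))
    return out


def glszm(lev, mask, lv):
    struct = np.ones((3, 3, 3), int)
    zones = []
    for g in lv:
        lab, nlab = ndimage.label(mask & (lev == g), structure=struct)
        for z in range(1, nlab + 1):
            zones.append((g, int((lab == z).sum())))
    smax = max(s for _, s in zones)
    P = np.zeros((len(lv), smax))
    li = {v: n for n, v in enumerate(lv)}
    for g, s in zones:
        P[li[g], s - 1] += 1
    nz = P.sum()
    npix = int(mask.sum())
    p = P / nz
    iv = lv.astype(float)
    jv = np.arange(1, smax + 1, dtype=float)
    pi = p.sum(1)
    pj = p.sum(0)
    si = P.sum(1)
    sj = P.sum(0)
    mui = (iv * pi).sum()
    muj = (jv * pj).sum()
    return {
        "GLSZM_GrayLevelNonUniformity": (si ** 2).sum() / nz,
        "GLSZM_GrayLevelNonUniformityNormalized": (si ** 2).sum() / nz ** 2,
        "GLSZM_GrayLevelVariance": ((iv - mui) ** 2 * pi).sum(),
        "GLSZM_HighGrayLevelZoneEmphasis": (iv ** 2 * pi).sum(),
        "GLSZM_LargeAreaEmphasis": (jv ** 2 * pj).sum(),
        "GLSZM_LargeAreaHighGrayLevelEmphasis": (np.outer(iv ** 2, jv ** 2) * p).sum(),
        "GLSZM_LargeAreaLowGrayLevelEmphasis": (np.outer(1 / iv ** 2, jv ** 2) * p).sum(),
        "GLSZM_LowGrayLevelZoneEmphasis": (pi / iv ** 2).sum(),
        "GLSZM_SizeZoneNonUniformity": (sj ** 2).sum() / nz,
        "GLSZM_SizeZoneNonUniformityNormalized": (sj ** 2).sum() / nz ** 2,
        "GLSZM_SmallAreaEmphasis": (pj / jv ** 2).sum(),
        "GLSZM_SmallAreaHighGrayLevelEmphasis": (np.outer(iv ** 2, 1 / jv ** 2) * p).sum(),
        "GLSZM_SmallAreaLowGrayLevelEmphasis": (np.outer(1 / iv ** 2, 1 / jv ** 2) * p).sum(),
        "GLSZM_ZoneEntropy": -(p[p > 0] * np.log2(p[p > 0] + EPS)).sum(),
        "GLSZM_ZonePercentage": nz / npix,
        "GLSZM_ZoneVariance": ((jv - muj) ** 2 * pj).sum(),
    }


def ngtdm(lev, mask, lv):
    d = mask.shape
    li = {v: n for n, v in enumerate(lv)}
    n_i = np.zeros(len(lv))
    s_i = np.zeros(len(lv))
    for (x, y, z) in np.argwhere(mask):
        nb = []
        for o in ALL26:
            nx, ny, nz = x + o[0], y + o[1], z + o[2]
            if 0 <= nx < d[0] and 0 <= ny < d[1] and 0 <= nz < d[2] and mask[nx, ny, nz]:
                nb.append(lev[nx, ny, nz])
        if nb:
            g = li[lev[x, y, z]]
            n_i[g] += 1
            s_i[g] += abs(lev[x, y, z] - np.mean(nb))
    nvp = n_i.sum()
    p_i = n_i / nvp
    keep = p_i > 0
    iv = lv[keep].astype(float)
    pv = p_i[keep]
    sv = s_i[keep]
    ngp = keep.sum()
    ps_sum = (pv * sv).sum()
    coarse = 1 / ps_sum if ps_sum > 0 else 1e6
    contrast = 0.0
    if ngp > 1:
        contrast = ((np.outer(pv, pv) * (iv[:, None] - iv[None, :]) ** 2).sum()
                    / (ngp * (ngp - 1)) * sv.sum() / nvp)
    ipi = iv * pv
    den = np.abs(ipi[:, None] - ipi[None, :]).sum()
    busy = ps_sum / den if den > 0 else 0.0
    dmat = np.abs(iv[:, None] - iv[None, :])
    psum = pv[:, None] + pv[None, :]
    smat = (pv * sv)[:, None] + (pv * sv)[None, :]
    complexity = (dmat * smat / psum).sum() / nvp
    strength = (psum * dmat ** 2).sum() / sv.sum() if sv.sum() > 0 else 0.0
    return {"NGTDM_Busyness": busy, "NGTDM_Coarseness": coarse,
            "NGTDM_Complexity": complexity, "NGTDM_Contrast": contrast,
            "NGTDM_Strength": strength}


def gldm(lev, mask, lv, alpha=0):
    d = mask.shape
    li = {v: n for n, v in enumerate(lv)}
    rows = []
    for (x, y, z) in np.argwhere(mask):
        dep = 0
        for o in ALL26:
            nx, ny, nz = x + o[0], y + o[1], z + o[2]
            if (0 <= nx < d[0] and 0 <= ny < d[1] and 0 <= nz < d[2]
                    and mask[nx, ny, nz]
                    and abs(int(lev[nx, ny, nz]) - int(lev[x, y, z])) <= alpha):
                dep += 1
        rows.append((li[lev[x, y, z]], dep + 1))
    dmax = max(j for _, j in rows)
    P = np.zeros((len(lv), dmax))
    for g, j in rows:
        P[g, j - 1] += 1
    nz = P.sum()
    p = P / nz
    iv = lv.astype(float)
    jv = np.arange(1, dmax + 1, dtype=float)
    pi = p.sum(1)
    pj = p.sum(0)
    si = P.sum(1)
    sj = P.sum(0)
    mui = (iv * pi).sum()
    muj = (jv * pj).sum()
    return {
        "GLDM_DependenceEntropy": -(p[p > 0] * np.log2(p[p > 0] + EPS)).sum(),
        "GLDM_DependenceNonUniformity": (sj ** 2).sum() / nz,
        "GLDM_DependenceNonUniformityNormalized": (sj ** 2).sum() / nz ** 2,
        "GLDM_DependenceVariance": ((jv - muj) ** 2 * pj).sum(),
        "GLDM_GrayLevelNonUniformity": (si ** 2).sum() / nz,
        "GLDM_GrayLevelVariance": ((iv - mui) ** 2 * pi).sum(),
        "GLDM_HighGrayLevelEmphasis": (iv ** 2 * pi).sum(),
        "GLDM_LargeDependenceEmphasis": (jv ** 2 * pj).sum(),
        "GLDM_LargeDependenceHighGrayLevelEmphasis": (np.outer(iv ** 2, jv ** 2) * p).sum(),
        "GLDM_LargeDependenceLowGrayLevelEmphasis": (np.outer(1 / iv ** 2, jv ** 2) * p).sum(),
        "GLDM_LowGrayLevelEmphasis": (pi / iv ** 2).sum(),
        "GLDM_SmallDependenceEmphasis": (pj / jv ** 2).sum(),
        "GLDM_SmallDependenceHighGrayLevelEmphasis": (np.outer(iv ** 2, 1 / jv ** 2) * p).sum(),
        "GLDM_SmallDependenceLowGrayLevelEmphasis": (np.outer(1 / iv ** 2, 1 / jv ** 2) * p).sum(),
    }


def main():
    val, mask, sp = phantom()
    vals = val[mask]
    levv = discretize(vals, BIN_WIDTH)
    lev = np.zeros(mask.shape, int)
    lev[mask] = levv
    lv = np.unique(levv)
    out = {}
    out.update(first_order(vals, levv, sp))
    out.update(shape(mask, sp))
    out.update(glcm(lev, mask, lv))
    out.update(glrlm(lev, mask, lv))
    out.update(glszm(lev, mask, lv))
    out.update(ngtdm(lev, mask, lv))
    out.update(gldm(lev, mask, lv))
    assert len(out) == 107, len(out)
    with open("inst/extdata/digital_phantom_oracle_features.csv", "w") as fh:
        fh.write("feature,value\n")
        for k in out:
            fh.write(f"{k},{out[k]:.12g}\n")
    print(f"wrote {len(out)} features; n_voxels={int(mask.sum())}, "
          f"levels={lv.min()}..{lv.max()} ({len(lv)} distinct)")


if __name__ == "__main__":
    main()
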