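# Independent brute-force oracles for the texture-matrix builders: plain
# triple loops over voxels and neighbourhoods, sharing no code with the
# package implementation.

oracle_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

oracle_glcm <- function(lev, mask, lv) {
  d <- dim(mask); ng <- length(lv)
  offs <- oracle_offsets()
  out <- array(0, c(ng, ng, nrow(offs)))
  co <- which(mask, arr.ind = TRUE)
  for (a in seq_len(nrow(offs))) {
    M <- matrix(0, ng, ng)
    for (r in seq_len(nrow(co))) {
      nb <- co[r, ] + offs[a, ]
      if (all(nb >= 1) && all(nb <= d) && mask[nb[1], nb[2], nb[3]]) {
        i <- match(lev[co[r, 1], co[r, 2], co[r, 3]], lv)
        j <- match(lev[nb[1], nb[2], nb[3]], lv)
        M[i, j] <- M[i, j] + 1
      }
    }
    out[, , a] <- M + t(M)
  }
  out
}

oracle_glrlm <- function(lev, mask, lv) {
  d <- dim(mask); ng <- length(lv)
  offs <- oracle_offsets()
  runs <- vector("list", nrow(offs))
  for (a in seq_len(nrow(offs))) {
    o <- offs[a, ]
    rl <- integer(0); rg <- integer(0)
    co <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(co))) {
      p <- co[r, ] - o
      prev_same <- all(p >= 1) && all(p <= d) && mask[p[1], p[2], p[3]] &&
        lev[p[1], p[2], p[3]] == lev[co[r, 1], co[r, 2], co[r, 3]]
      if (prev_same) next
      len <- 1L
      cur <- co[r, ] + o
      while (all(cur >= 1) && all(cur <= d) && mask[cur[1], cur[2], cur[3]] &&
             lev[cur[1], cur[2], cur[3]] == lev[co[r, 1], co[r, 2], co[r, 3]]) {
        len <- len + 1L
        cur <- cur + o
      }
      rl <- c(rl, len)
      rg <- c(rg, match(lev[co[r, 1], co[r, 2], co[r, 3]], lv))
    }
    runs[[a]] <- list(g = rg, l = rl)
  }
  maxlen <- max(unlist(lapply(runs, `[[`, "l")))
  out <- array(0, c(ng, maxlen, nrow(offs)))
  for (a in seq_along(runs)) {
    for (i in seq_along(runs[[a]]$g)) {
      out[runs[[a]]$g[i], runs[[a]]$l[i], a] <-
        out[runs[[a]]$g[i], runs[[a]]$l[i], a] + 1
    }
  }
  out
}

# zones by flood fill (26-connected, equal level)
oracle_glszm <- function(lev, mask, lv) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  zones <- list()
  co <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    v <- co[r, ]
    if (visited[v[1], v[2], v[3]]) next
    g <- lev[v[1], v[2], v[3]]
    queue <- list(v)
    visited[v[1], v[2], v[3]] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- cur + c(dx, dy, dz)
        if (all(nb >= 1) && all(nb <= d) && !visited[nb[1], nb[2], nb[3]] &&
            mask[nb[1], nb[2], nb[3]] && lev[nb[1], nb[2], nb[3]] == g) {
          visited[nb[1], nb[2], nb[3]] <- TRUE
          queue <- c(queue, list(nb))
        }
      }
    }
    zones <- c(zones, list(c(match(g, lv), size)))
  }
  smax <- max(vapply(zones, `[`, numeric(1), 2))
  M <- matrix(0, length(lv), smax)
  for (z in zones) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

oracle_ngtdm <- function(lev, mask, lv) {
  d <- dim(mask); ng <- length(lv)
  n <- integer(ng); s <- numeric(ng)
  co <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    vals <- numeric(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- co[r, ] + c(dx, dy, dz)
      if (all(nb >= 1) && all(nb <= d) && mask[nb[1], nb[2], nb[3]]) {
        vals <- c(vals, lev[nb[1], nb[2], nb[3]])
      }
    }
    if (length(vals) > 0) {
      i <- match(lev[co[r, 1], co[r, 2], co[r, 3]], lv)
      n[i] <- n[i] + 1L
      s[i] <- s[i] + abs(lev[co[r, 1], co[r, 2], co[r, 3]] - mean(vals))
    }
  }
  list(n = n, s = s)
}

oracle_gldm <- function(lev, mask, lv, alpha = 0) {
  d <- dim(mask)
  rows <- list()
  co <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    dep <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- co[r, ] + c(dx, dy, dz)
      if (all(nb >= 1) && all(nb <= d) && mask[nb[1], nb[2], nb[3]] &&
          abs(lev[nb[1], nb[2], nb[3]] - lev[co[r, 1], co[r, 2], co[r, 3]]) <= alpha) {
        dep <- dep + 1L
      }
    }
    rows <- c(rows, list(c(match(lev[co[r, 1], co[r, 2], co[r, 3]], lv), dep + 1L)))
  }
  dmax <- max(vapply(rows, `[`, numeric(1), 2))
  M <- matrix(0, length(lv), dmax)
  for (z in rows) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

# random discretized VOI on a small grid
random_level_grid <- function(seed, d = c(4, 4, 3), n_levels = 4, p_mask = 0.8) {
  set.seed(seed)
  lev <- array(sample(seq_len(n_levels), prod(d), TRUE), d)
  mask <- array(runif(prod(d)) < p_mask, d)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  lev[!mask] <- NA_integer_
  list(lev = lev, mask = mask)
}

# small, fast phantom settings shared across tests
tiny_scanner <- function(noise = 0, fwhm = 0, grid = c(36L, 36L, 30L)) {
  scanner_profile("tiny", c(2, 2, 2.4), fwhm, noise, grid)
}
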