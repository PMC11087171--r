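# Shared fixtures and independent brute-force oracles.

tiny_geometry <- function(shape = c(8, 8, 6), spacing = c(1, 1, 1.5)) {
  volume_geometry(shape, spacing)
}

random_mask <- function(geometry, p = 0.15, name = "m", role = "OAR") {
  occ <- array(stats::runif(prod(geometry$shape)) < p, geometry$shape)
  structure_mask(occ, geometry, name, role)
}

# all voxel-center coordinates of a geometry, as an n x 3 matrix
voxel_center_matrix <- function(geometry) {
  idx <- arrayInd(seq_len(prod(geometry$shape)), geometry$shape)
  sweep(sweep(idx - 1, 2, geometry$spacing, `*`), 2, geometry$origin, `+`)
}

# brute-force Euclidean dilation: output voxel true iff its center is within
# radius of some true voxel center (all-pairs distances)
bf_expand <- function(mask, radius_mm) {
  pts <- voxel_center_matrix(mask$geometry)
  src <- pts[as.vector(mask$occupancy), , drop = FALSE]
  out <- rep(FALSE, nrow(pts))
  if (nrow(src) > 0) {
    for (i in seq_len(nrow(pts))) {
      d2 <- (src[, 1] - pts[i, 1])^2 + (src[, 2] - pts[i, 2])^2 +
        (src[, 3] - pts[i, 3])^2
      out[i] <- any(d2 <= radius_mm^2 + 1e-9)
    }
  }
  structure_mask(array(out, mask$geometry$shape), mask$geometry,
                 mask$name, mask$role)
}

# counting oracle for V / mean metrics
bf_v_pct <- function(dose_vals, thr) 100 * mean(dose_vals >= thr - 1e-12)

# bracketing oracle for D_cc: the interpolated value must lie between the
# doses of the voxels bracketing the requested volume on the descending sort
bf_dcc_bounds <- function(dose_vals, voxel_cc, cc) {
  ds <- sort(dose_vals, decreasing = TRUE)
  k_hi <- max(1, floor(cc / voxel_cc))          # inside the hottest k_hi voxels
  k_lo <- min(length(ds), ceiling(cc / voxel_cc))
  c(lower = ds[k_lo], upper = ds[k_hi])
}

# dense brute-force gamma oracle: independent bilinear interpolation at
# arbitrary positions, exhaustive search on the dense candidate lattice
bf_gamma_2d <- function(ref, ev, spacing, dose_tol_pct = 3, dta = 2,
                        thresh_pct = 10, search_radius = 3 * dta,
                        step = dta / 10) {
  norm <- max(ref)
  tol <- dose_tol_pct / 100 * norm
  thr <- thresh_pct / 100 * norm
  nx <- nrow(ev); ny <- ncol(ev)
  interp <- function(x, y) {
    fx <- x / spacing[1]; fy <- y / spacing[2]
    i <- min(max(floor(fx), 0), nx - 2); j <- min(max(floor(fy), 0), ny - 2)
    wx <- fx - i; wy <- fy - j
    (1 - wx) * (1 - wy) * ev[i + 1, j + 1] + wx * (1 - wy) * ev[i + 2, j + 1] +
      (1 - wx) * wy * ev[i + 1, j + 2] + wx * wy * ev[i + 2, j + 2]
  }
  offs <- expand.grid(dx = seq(-search_radius, search_radius, by = step),
                      dy = seq(-search_radius, search_radius, by = step))
  offs <- offs[offs$dx^2 + offs$dy^2 <= search_radius^2 + 1e-9, ]
  gmap <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (ref[i, j] < thr) next
      x0 <- (i - 1) * spacing[1]; y0 <- (j - 1) * spacing[2]
      best <- Inf
      for (k in seq_len(nrow(offs))) {
        x <- x0 + offs$dx[k]; y <- y0 + offs$dy[k]
        if (x < 0 || y < 0 || x > (nx - 1) * spacing[1] ||
            y > (ny - 1) * spacing[2]) next
        g2 <- ((interp(x, y) - ref[i, j]) / tol)^2 +
          (offs$dx[k]^2 + offs$dy[k]^2) / dta^2
        if (g2 < best) best <- g2
      }
      gmap[i, j] <- sqrt(best)
    }
  }
  gmap
}

# permutation oracle for the exact rank-sum p-value, built on the
# Mann-Whitney U statistic (pair counting, ties counted one half) rather
# than rank sums
bf_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  u_of <- function(av, bv) {
    sum(outer(av, bv, `>`)) + 0.5 * sum(outer(av, bv, `==`))
  }
  u_obs <- u_of(a, b)
  subsets <- utils::combn(n + m, n)
  us <- apply(subsets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# a small shared phantom for the heavier end-to-end tests (built once)
shared_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_phantom(phantom_spec("LEFT", c(64, 64, 48), c(4, 4, 4)))
    }
    cache
  }
})
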