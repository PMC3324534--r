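# Shared in-code fixtures and independent oracles.

rms <- function(x) sqrt(mean(x^2))

# centered-disk attenuation slice (nx x nx x 1) and its geometry
disk_volume <- function(n = 64, mu = 0.1, radius = 20) {
  xy <- (1:n) - (n + 1) / 2
  rr <- sqrt(outer(xy^2, xy^2, "+"))
  list(vol = array((rr <= radius) * mu, c(n, n, 1)), rr = rr,
       mu = mu, radius = radius)
}

disk_sinogram <- function(n = 64, mu = 0.1, radius = 20, vox = 0.1,
                          angles = seq(0, 179, by = 1), I0 = 1) {
  d <- disk_volume(n, mu, radius)
  pr <- forward_project(d$vol, angles, "transmission", I0 = I0,
                        voxel_size = vox)
  list(sino = projection_sinogram(pr, 1), disk = d, vox = vox,
       angles = angles)
}

# voxelized solid prolate ellipsoid mask (optionally truncated), cheap
# (no probe/EDT machinery) for fit-recovery sweeps
ellipsoid_mask <- function(n = 56, voxel = 0.2, semi_axes = c(3, 3, 4.6),
                           center = c(0, 0, 0), rotation = diag(3),
                           truncation_fraction = NULL) {
  ax <- lapply(1:3, function(k) (seq_len(n) - (n + 1) / 2) * voxel)
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  q <- sweep(g, 2, center) %*% rotation
  inside <- (q[, 1] / semi_axes[1])^2 + (q[, 2] / semi_axes[2])^2 +
    (q[, 3] / semi_axes[3])^2 <= 1
  if (!is.null(truncation_fraction))
    inside <- inside & q[, 3] >= semi_axes[3] * (1 - 2 * truncation_fraction)
  array(inside, c(n, n, n))
}

# toggle a fraction of boundary voxels in or out (1-voxel jitter)
jitter_mask <- function(mask, p = 0.3) {
  grow <- mask | (optheart:::.dilate6(mask) & !mask &
                    array(runif(length(mask)) < p / 2, dim(mask)))
  bound <- optheart:::.boundary6(grow)
  flip <- bound & array(runif(length(mask)) < p, dim(mask))
  out <- grow
  out[flip] <- !out[flip]
  out
}

# Independent filtered-backprojection oracle: explicit DFT-matrix
# filtering and per-pixel backprojection loops, sharing no code with
# fbp_slice beyond the mathematical definition.
fbp_bruteforce <- function(sino, angles_deg, filter = "shepp-logan",
                           voxel_size = 1) {
  n <- nrow(sino); nA <- ncol(sino)
  M <- max(64, 2^ceiling(log2(2 * n)))
  W <- exp(-2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  fr <- c(0:(M / 2), -(M / 2 - 1):-1) / M
  ramp <- 2 * abs(fr)
  h <- switch(filter,
    "ram-lak" = ramp,
    "shepp-logan" = {
      s <- rep(1, M); nz <- fr != 0
      s[nz] <- sin(pi * fr[nz]) / (pi * fr[nz]); ramp * s
    },
    "hann" = ramp * 0.5 * (1 + cos(2 * pi * fr)))
  q <- matrix(0, n, nA)
  for (k in seq_len(nA)) {
    p <- c(sino[, k], rep(0, M - n))
    Q <- Re(Conj(W) %*% (h * (W %*% p))) / M
    q[, k] <- Q[seq_len(n)]
  }
  c0 <- (n + 1) / 2
  rec <- matrix(0, n, n)
  th <- angles_deg * pi / 180
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- i - c0; y <- j - c0
    s <- 0
    for (k in seq_len(nA)) {
      t <- x * cos(th[k]) + y * sin(th[k]) + c0
      i0 <- floor(t)
      if (i0 >= 1 && i0 <= n - 1) {
        f2 <- t - i0
        s <- s + (1 - f2) * q[i0, k] + f2 * q[i0 + 1, k]
      }
    }
    rec[i, j] <- s
  }
  dth <- stats::median(diff(angles_deg)) * pi / 180
  span <- diff(range(angles_deg)) + stats::median(diff(angles_deg))
  rec * dth / 2 / (if (span > 270) 2 else 1) / voxel_size
}

# small standard phantom used across tests
small_phantom <- function(n = 48, voxel = 0.22, ...) {
  make_lv_phantom(grid_shape = rep(n, 3), voxel_size = voxel, ...)
}
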