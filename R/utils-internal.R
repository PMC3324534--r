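# Internal numerics shared across modules. All masks are logical 3D arrays;
# all dense interpolation is vectorized over flat voxel indices.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## ---- array shifting and 6-connected morphology ----

# integer shift with zero (FALSE) fill
.shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (abs(s[k]) >= d[k]) return(out)
    if (s[k] >= 0) {
      src[[k]] <- seq_len(d[k] - s[k])
      dst[[k]] <- seq_len(d[k] - s[k]) + s[k]
    } else {
      src[[k]] <- seq_len(d[k] + s[k]) - s[k]
      dst[[k]] <- seq_len(d[k] + s[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.offsets6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

.erode6 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(.offsets6))) out <- out & .shift3(mask, .offsets6[i, ])
  out
}

.dilate6 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(.offsets6))) out <- out | .shift3(mask, .offsets6[i, ])
  out
}

# morphological closing with an approximately spherical (iterated 6-conn)
# structuring element of radius r voxels
.close6 <- function(mask, r) {
  out <- mask
  for (i in seq_len(r)) out <- .dilate6(out)
  for (i in seq_len(r)) out <- .erode6(out)
  out
}

# boundary voxels: in mask but lost under 6-connected erosion
.boundary6 <- function(mask) mask & !.erode6(mask)

# largest 6-connected component, BFS on flat indices
.largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(mask)
  nxy <- d[1] * d[2]
  cur <- 0L
  sizes <- integer(0)
  for (seed in idx) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    lab[seed] <- cur
    n_comp <- 1L
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      # decode flat index -> (i,j,k)
      k <- (v - 1L) %/% nxy
      r2 <- (v - 1L) %% nxy
      j <- r2 %/% d[1]
      i <- r2 %% d[1]
      for (o in 1:6) {
        ii <- i + .offsets6[o, 1]; jj <- j + .offsets6[o, 2]; kk <- k + .offsets6[o, 3]
        ok <- ii >= 0L & ii < d[1] & jj >= 0L & jj < d[2] & kk >= 0L & kk < d[3]
        w <- ii[ok] + jj[ok] * d[1] + kk[ok] * nxy + 1L
        w <- w[mask[w] & lab[w] == 0L]
        if (length(w)) {
          lab[w] <- cur
          queue <- c(queue, w)
          n_comp <- n_comp + length(w)
        }
      }
      queue <- unique(queue)
    }
    sizes[cur] <- n_comp
  }
  lab == which.max(sizes)
}

## ---- Euclidean distance transform ----

# 1D squared distance transform (lower envelope of parabolas); Inf entries
# contribute no parabola but are still queried
.dt1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1] <- fin[1]
  z[1] <- -Inf; z[2] <- Inf
  for (q in fin[-1]) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Euclidean distance (mm) from every voxel to the nearest TRUE voxel of mask.
# Isotropic voxels; separable Felzenszwalb-Huttenlocher passes.
.edt3 <- function(mask, voxel_size = 1) {
  d <- dim(mask)
  g <- array(ifelse(mask, 0, Inf), d)
  if (!any(mask)) return(array(Inf, d))
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    col <- g[, j, k]
    if (all(is.infinite(col)) || all(col == 0)) next
    g[, j, k] <- .dt1d(col)
  }
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) {
    row <- g[i, , k]
    if (all(row == 0)) next
    g[i, , k] <- .dt1d(row)
  }
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    line <- g[i, j, ]
    if (all(line == 0)) next
    g[i, j, ] <- .dt1d(line)
  }
  sqrt(g) * voxel_size
}

## ---- interpolation ----

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates (n x 3 matrix). Points outside the grid return `outside`.
.trilinear <- function(vol, pts, outside = NA_real_) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  base <- (x0 - 1) + (y0 - 1) * d[1] + (z0 - 1) * d[1] * d[2] + 1
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- vol[base];            v100 <- vol[base + sx]
  v010 <- vol[base + sy];       v110 <- vol[base + sx + sy]
  v001 <- vol[base + sz];       v101 <- vol[base + sx + sz]
  v011 <- vol[base + sy + sz];  v111 <- vol[base + sx + sy + sz]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

## ---- rotation ----

# Rodrigues rotation matrix for angle (deg) about unit axis
.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Resample a 3D array rotated by `rot` about `center` (1-based voxel coords):
# out(p) = vol(R^T (p - c) + c)
.rotate_volume <- function(vol, rot, center, outside = 0) {
  d <- dim(vol)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  p <- sweep(g, 2, center) %*% rot  # rows: (p - c)^T R = (R^T (p-c))^T
  p <- sweep(p, 2, center, "+")
  array(.trilinear(vol, p, outside = outside), d)
}

## ---- misc ----

# centered moving average with edge replication, window forced odd >= 3
.moving_average <- function(x, window) {
  w <- max(3L, as.integer(window))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1L):(h + length(x))]
}

# FFT sample frequencies in cycles/sample, length n
.fftfreq <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / n
}
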