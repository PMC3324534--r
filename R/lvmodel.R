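#' Left-ventricle ellipsoid model
#'
#' The thick-walled truncated-ellipsoid description of the left ventricle:
#' a prolate ellipsoid (equal short semi-axes) whose long axis is the local
#' z axis, truncated at a base plane so that `truncation_fraction` of the
#' long-axis extent (2c) is retained from the apex (local +z pole). The
#' focal distance `f = sqrt(c^2 - a^2)` defines the prolate spheroidal
#' coordinate frame used by all cartography.
#'
#' @param center ellipsoid center, mm (world frame).
#' @param rotation 3x3 orthonormal matrix, columns = local axes in world
#'   coordinates (third column = long axis).
#' @param semi_axes `c(a, b, c)` in mm with `c` the long semi-axis. `a` and
#'   `b` are averaged to enforce prolate symmetry.
#' @param truncation_fraction fraction of the long-axis extent retained
#'   from the apex (default 3/4; the basal quarter is flagged, not used in
#'   quantitative summaries).
#' @return An object of class `lv_ellipsoid` with fields `center`,
#'   `rotation`, `semi_axes`, `focal_distance` (NA and
#'   `oblate_degenerate = TRUE` when `c <= a`), `truncation_fraction`.
#' @examples
#' m <- lv_ellipsoid(c(0, 0, 0), diag(3), c(3, 3, 4.6))
#' m$focal_distance
#' @export
lv_ellipsoid <- function(center, rotation = diag(3), semi_axes,
                         truncation_fraction = 0.75) {
  .assert(length(center) == 3L, "`center` must have length 3")
  .assert(all(dim(rotation) == c(3L, 3L)) &&
            max(abs(crossprod(rotation) - diag(3))) < 1e-8,
          "`rotation` must be a 3x3 orthonormal matrix")
  .assert(length(semi_axes) == 3L && all(semi_axes > 0),
          "`semi_axes` must be 3 positive lengths")
  a <- mean(semi_axes[1:2])
  cc <- semi_axes[3]
  # within 1% of spherical the prolate frame is numerically meaningless
  oblate <- cc <= a * 1.01
  f <- if (oblate) NA_real_ else sqrt(cc^2 - a^2)
  structure(list(center = as.numeric(center), rotation = rotation,
                 semi_axes = c(a, a, cc), focal_distance = f,
                 oblate_degenerate = oblate,
                 truncation_fraction = truncation_fraction),
            class = "lv_ellipsoid")
}

#' @export
print.lv_ellipsoid <- function(x, ...) {
  cat("<lv_ellipsoid>\n")
  cat(sprintf("  center      (%.3f, %.3f, %.3f) mm\n", x$center[1],
              x$center[2], x$center[3]))
  cat(sprintf("  semi-axes   a = b = %.3f, c = %.3f mm\n", x$semi_axes[1],
              x$semi_axes[3]))
  if (x$oblate_degenerate) {
    cat("  focal dist  undefined (oblate-degenerate: c <= a)\n")
  } else {
    cat(sprintf("  focal dist  f = %.3f mm\n", x$focal_distance))
  }
  cat(sprintf("  truncation  %.0f%% of long axis retained from apex\n",
              100 * x$truncation_fraction))
  if (!is.null(x$residual_rms))
    cat(sprintf("  fit residual RMS %.4f (relative radial)\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.lv_ellipsoid <- function(object, ...) {
  c(cx = object$center[1], cy = object$center[2], cz = object$center[3],
    a = object$semi_axes[1], c = object$semi_axes[3],
    f = object$focal_distance)
}

#' @export
summary.lv_ellipsoid <- function(object, ...) {
  print(object)
  if (!is.null(object$n_surface_voxels))
    cat(sprintf("  fitted on %d epicardial surface voxels\n",
                object$n_surface_voxels))
  invisible(object)
}

# polar angle at which the base truncation plane cuts the reference
# ellipsoid surface: z_local = c cos(mu_trunc) = c (1 - 2 tf)
#' Truncation polar angle of the base plane
#'
#' The `mu` level above which the map region is basal (cut away by the
#' truncation plane) and excluded from quantitative summaries.
#' @param model an [lv_ellipsoid].
#' @return angle in radians, in (0, pi].
#' @export
truncation_mu <- function(model) acos(1 - 2 * model$truncation_fraction)

## ---- world/grid coordinate plumbing ----

# world mm of 1-based voxel index (origin at grid center), and inverse
.index_to_mm <- function(idx, d, voxel_size)
  sweep(idx, 2, (d + 1) / 2) * voxel_size
.mm_to_index <- function(p, d, voxel_size)
  sweep(p / voxel_size, 2, (d + 1) / 2, "+")

## ---- long-axis fit ----

#' Fit the left-ventricular long axis from a segmentation mask
#'
#' Least-squares line through the per-slice centroids of the mask's
#' short-axis cross-sections, taken along the grid axis of greatest mask
#' extent.
#'
#' @param lv_mask logical 3D array, the filled LV segmentation.
#' @param voxel_size voxel edge, mm.
#' @return list with `point` (a point on the axis, mm), `direction` (unit
#'   vector, world frame, oriented towards positive slice index),
#'   `n_slices` used, and `degenerate` (TRUE when the mask is too close to
#'   spherical for a stable axis, extent ratio < 1.1).
#' @export
fit_long_axis <- function(lv_mask, voxel_size = 1) {
  .assert(is.array(lv_mask) && length(dim(lv_mask)) == 3L,
          "`lv_mask` must be a 3D array")
  .assert(any(lv_mask), "empty mask")
  d <- dim(lv_mask)
  idx <- which(lv_mask, arr.ind = TRUE)
  occ <- apply(idx, 2, function(v) length(unique(v)))
  .assert(all(occ >= 3L),
          "need at least 3 occupied slices for an axis fit (planar mask)")
  p <- .index_to_mm(idx, d, voxel_size)
  ctr <- colMeans(p)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  ratio <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
  # start from the principal direction, then iterate the centroid-line fit
  # with slices perpendicular to the current axis: slicing along any other
  # direction would trace a conjugate diameter, not the symmetry axis
  dir <- ev$vectors[, 1]
  n_slices <- 0L
  for (it in 1:3) {
    t_coord <- drop(sweep(p, 2, ctr) %*% dir)
    bin <- round(t_coord / voxel_size)
    tab <- sort(unique(bin))
    if (it == 1L)
      .assert(length(tab) >= 3L,
              "need at least 3 occupied slices for an axis fit")
    cent <- t(vapply(tab, function(b)
      colMeans(p[bin == b, , drop = FALSE]), numeric(3)))
    w <- as.numeric(table(factor(bin, levels = tab)))
    tb <- tab * voxel_size
    v <- vapply(1:3, function(k)
      stats::lm.wfit(cbind(1, tb), cent[, k], w)$coefficients[2], numeric(1))
    dir_new <- v / sqrt(sum(v^2))
    if (sum(dir_new * dir) < 0) dir_new <- -dir_new
    dir <- dir_new
    n_slices <- length(tab)
  }
  dom <- which.max(abs(dir))
  if (dir[dom] < 0) dir <- -dir
  list(point = ctr, direction = dir, n_slices = n_slices,
       degenerate = ratio < 1.1)
}

# orthonormal frame with given unit z axis
.frame_from_axis <- function(zax) {
  zax <- zax / sqrt(sum(zax^2))
  up <- if (abs(zax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  xax <- up - sum(up * zax) * zax
  xax <- xax / sqrt(sum(xax^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  cbind(xax, yax, zax, deparse.level = 0)
}

## ---- ellipsoid fit ----

#' Fit a coaxial prolate ellipsoid to the epicardial surface
#'
#' Extracts the epicardial surface voxels of the (filled) LV mask as the
#' 6-connectivity erosion difference, drops the flat base-cut facet, and
#' fits a coaxial ellipsoid in the long-axis frame: first a linear least
#' squares solve of the algebraic form
#' `A (x^2 + y^2) + B z^2 + C x + D y + E z = 1`, then a Nelder-Mead
#' geometric refinement of center and semi-axes on the normalized radial
#' residuals.
#'
#' @param lv_mask logical 3D array, filled LV segmentation.
#' @param axis result of [fit_long_axis()]; fitted from the mask when NULL.
#' @param voxel_size voxel edge, mm.
#' @param truncation_fraction stored on the returned model.
#' @param refine logical: run the geometric refinement stage.
#' @return An [lv_ellipsoid] (subclass `lv_ellipsoid_fit`) with
#'   `residual_rms` (relative radial residual), `n_surface_voxels`, and
#'   `axis` attached. `oblate_degenerate` is TRUE when the fitted `c` does
#'   not exceed `a` (focal distance undefined).
#' @examples
#' ph <- make_lv_phantom(grid_shape = c(48, 48, 48), voxel_size = 0.25)
#' fit <- fit_lv_ellipsoid(ph$lv_mask, voxel_size = 0.25)
#' coef(fit)
#' @export
fit_lv_ellipsoid <- function(lv_mask, axis = NULL, voxel_size = 1,
                             truncation_fraction = 0.75, refine = TRUE) {
  .assert(any(lv_mask), "empty mask")
  d <- dim(lv_mask)
  if (is.null(axis)) axis <- fit_long_axis(lv_mask, voxel_size)
  R <- .frame_from_axis(axis$direction)
  surf <- which(.boundary6(lv_mask), arr.ind = TRUE)
  p <- .index_to_mm(surf, d, voxel_size)
  q <- sweep(p, 2, axis$point) %*% R  # local frame, origin on the axis
  # drop the flat truncation facet: the long-axis end with the larger
  # terminal cross-section is the base cut
  zr <- range(q[, 3])
  lo_n <- sum(q[, 3] < zr[1] + 2 * voxel_size)
  hi_n <- sum(q[, 3] > zr[2] - 2 * voxel_size)
  keep <- if (lo_n > hi_n) q[, 3] >= zr[1] + 2 * voxel_size
          else q[, 3] <= zr[2] - 2 * voxel_size
  q <- q[keep, , drop = FALSE]
  .assert(nrow(q) >= 12L, "too few epicardial surface voxels to fit")

  # algebraic linear LS: A (x^2+y^2) + B z^2 + C x + D y + E z = 1
  algebraic <- function(q) {
    X <- cbind(q[, 1]^2 + q[, 2]^2, q[, 3]^2, q[, 1], q[, 2], q[, 3])
    beta <- stats::lm.fit(X, rep(1, nrow(q)))$coefficients
    A <- beta[1]; B <- beta[2]
    .assert(is.finite(A) && is.finite(B) && A > 0 && B > 0,
            "ellipsoid fit did not converge (non-elliptic algebraic solution)")
    G <- 1 + (beta[3]^2 + beta[4]^2) / (4 * A) + beta[5]^2 / (4 * B)
    c(-beta[3] / (2 * A), -beta[4] / (2 * A), -beta[5] / (2 * B),
      sqrt(G / A), sqrt(G / B))
  }
  resid_fun <- function(par, q) {
    phi <- ((q[, 1] - par[1])^2 + (q[, 2] - par[2])^2) / par[4]^2 +
      (q[, 3] - par[3])^2 / par[5]^2
    sqrt(pmax(phi, 0)) - 1
  }
  refine_fun <- function(par, q) {
    if (!refine) return(par)
    stats::optim(par, function(p) sum(resid_fun(p, q)^2),
                 method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))$par
  }
  # robust trimming: residual outliers (stray voxels, remnants of the
  # base-cut facet) are dropped and the fit repeated
  qk <- q
  par <- refine_fun(algebraic(qk), qk)
  for (it in 1:2) {
    res <- resid_fun(par, qk)
    s <- stats::mad(res)
    keep2 <- abs(res - stats::median(res)) <= 3 * max(s, 1e-6)
    if (all(keep2) || sum(keep2) < 12L) break
    qk <- qk[keep2, , drop = FALSE]
    par <- refine_fun(algebraic(qk), qk)
  }
  res <- resid_fun(par, qk)
  center_world <- axis$point + as.numeric(R %*% par[1:3])
  # boundary voxel centers lie ~half a voxel inside the continuous surface
  model <- lv_ellipsoid(center_world, R,
                        c(par[4], par[4], par[5]) + voxel_size / 2,
                        truncation_fraction)
  model$residual_rms <- sqrt(mean(res^2))
  model$n_surface_voxels <- nrow(q)
  model$axis <- axis
  class(model) <- c("lv_ellipsoid_fit", class(model))
  model
}

## ---- prolate spheroidal coordinates ----

#' Prolate spheroidal to Cartesian coordinates
#'
#' The prolate spheroidal frame of an LV model: radial coordinate `lam`
#' (dimensionless, >= 0), polar angle `mu` in `[0, pi]` with `mu = 0` at
#' the apex pole, azimuth `theta` in `[0, 2 pi)`. In the local frame
#' `x = f sinh(lam) sin(mu) cos(theta)`,
#' `y = f sinh(lam) sin(mu) sin(theta)`,
#' `z = f cosh(lam) cos(mu)`, then rotated and translated by the model.
#' Surfaces of constant `lam` are confocal prolate ellipsoids with
#' semi-axes `f sinh(lam)` (short) and `f cosh(lam)` (long).
#'
#' @param coord numeric vector `c(lam, mu, theta)` or an n x 3 matrix.
#' @param model an [lv_ellipsoid] with a defined focal distance.
#' @return n x 3 matrix of world mm points.
#' @export
prolate_to_cartesian <- function(coord, model) {
  .assert(!isTRUE(model$oblate_degenerate),
          "model is oblate-degenerate: prolate frame undefined")
  if (is.null(dim(coord))) coord <- matrix(coord, ncol = 3)
  f <- model$focal_distance
  lam <- coord[, 1]; mu <- coord[, 2]; th <- coord[, 3]
  q <- cbind(f * sinh(lam) * sin(mu) * cos(th),
             f * sinh(lam) * sin(mu) * sin(th),
             f * cosh(lam) * cos(mu))
  sweep(q %*% t(model$rotation), 2, model$center, "+")
}

#' Cartesian to prolate spheroidal coordinates
#'
#' Inverse of [prolate_to_cartesian()], computed through the conformal
#' identity `z + i rho = f cosh(lam + i mu)` with `rho` the distance from
#' the long axis. Unique off the focal segment; on the long axis the
#' azimuth is conventionally 0 and the result carries a `degenerate`
#' attribute marking those rows.
#'
#' @param point numeric vector of length 3 or n x 3 matrix, world mm.
#' @param model an [lv_ellipsoid] with a defined focal distance.
#' @return n x 3 matrix with columns `lam`, `mu`, `theta`; attribute
#'   `degenerate` flags on-axis points.
#' @export
cartesian_to_prolate <- function(point, model) {
  .assert(!isTRUE(model$oblate_degenerate),
          "model is oblate-degenerate: prolate frame undefined")
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  f <- model$focal_distance
  q <- sweep(point, 2, model$center) %*% model$rotation
  rho <- sqrt(q[, 1]^2 + q[, 2]^2)
  w <- complex(real = q[, 3], imaginary = rho) / f
  # principal acosh: Re >= 0, Im in [0, pi] for Im(w) >= 0
  u <- log(w + sqrt(w - 1) * sqrt(w + 1))
  lam <- pmax(Re(u), 0)
  mu <- pmin(pmax(Im(u), 0), pi)
  degenerate <- rho < 1e-12 * max(f, 1)
  th <- atan2(q[, 2], q[, 1]) %% (2 * pi)
  th[degenerate] <- 0
  out <- cbind(lam = lam, mu = mu, theta = th)
  attr(out, "degenerate") <- degenerate
  out
}

# lam value of the confocal ellipsoid through the model's epicardial
# surface (equivalently acosh(c/f))
.lam_of_model <- function(model) acosh(model$semi_axes[3] / model$focal_distance)

## ---- wall thickness ----

#' Myocardial wall thickness on the prolate angular grid
#'
#' For every `(mu, theta)` node, marches outward along the prolate radial
#' (`lam`) direction and takes the distance in mm between the endocardial
#' and epicardial surface crossings (the last exits from the filled endo-
#' and epicardial masks).
#'
#' @param epicardium_mask,endocardium_mask logical 3D arrays: the filled
#'   epicardial region (myocardium + cavity) and the filled cavity.
#' @param model an [lv_ellipsoid].
#' @param grid a [map_grid()].
#' @param voxel_size voxel edge, mm.
#' @param n_lam radial marching resolution.
#' @return A [surface_map] of thickness in mm; nodes without both
#'   crossings are invalid (not zero).
#' @export
wall_thickness <- function(epicardium_mask, endocardium_mask, model,
                           grid = map_grid(), voxel_size = 1,
                           n_lam = 160L) {
  .assert(all(dim(epicardium_mask) == dim(endocardium_mask)),
          "masks must share shape")
  d <- dim(epicardium_mask)
  lam_max <- 1.6 * .lam_of_model(model) + 0.2
  lam_seq <- seq(0, lam_max, length.out = n_lam)
  nn <- grid$n_mu * grid$n_theta
  nodes <- cbind(mu = rep(grid$mu, times = grid$n_theta),
                 theta = rep(grid$theta, each = grid$n_mu))
  # points: (node, lam) -> world mm -> voxel index
  co <- cbind(lam = rep(lam_seq, each = nn),
              mu = rep(nodes[, 1], times = n_lam),
              theta = rep(nodes[, 2], times = n_lam))
  pts <- prolate_to_cartesian(co, model)
  idx <- .mm_to_index(pts, d, voxel_size)
  ri <- round(idx)
  ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] & ri[, 2] >= 1 & ri[, 2] <= d[2] &
    ri[, 3] >= 1 & ri[, 3] <= d[3]
  flat <- rep(NA_integer_, nrow(ri))
  flat[ok] <- ri[ok, 1] + (ri[ok, 2] - 1) * d[1] + (ri[ok, 3] - 1) * d[1] * d[2]
  in_epi <- matrix(FALSE, nn, n_lam)
  in_endo <- matrix(FALSE, nn, n_lam)
  in_epi[ok] <- epicardium_mask[flat[ok]]
  in_endo[ok] <- endocardium_mask[flat[ok]]
  last_true <- function(m) {
    hit <- rowSums(m) > 0
    li <- max.col(sweep(m, 2, seq_len(ncol(m)), "*"), ties.method = "last")
    li[!hit] <- NA_integer_
    li
  }
  li_epi <- last_true(in_epi)
  li_endo <- last_true(in_endo)
  thick <- rep(NA_real_, nn)
  valid <- !is.na(li_epi) & !is.na(li_endo) & li_epi < n_lam
  iv <- which(valid)
  if (length(iv)) {
    p_epi <- prolate_to_cartesian(cbind(lam_seq[li_epi[iv]],
                                        nodes[iv, 1], nodes[iv, 2]), model)
    p_endo <- prolate_to_cartesian(cbind(lam_seq[li_endo[iv]],
                                         nodes[iv, 1], nodes[iv, 2]), model)
    thick[iv] <- sqrt(rowSums((p_epi - p_endo)^2))
  }
  surface_map(matrix(thick, grid$n_mu, grid$n_theta),
              valid = matrix(valid, grid$n_mu, grid$n_theta),
              grid = grid, truncation_mu = truncation_mu(model),
              units = "mm", kind = "cylindrical")
}
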