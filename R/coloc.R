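# Dual-probe colocalization: Manders-type overlap coefficient as a
# cross-correlation function (CCF) over integer translations and over
# rotations about the fitting ellipsoid's principal axes, with FWHM
# summaries of the CCF peak.

#' Overlap coefficient of two volumes
#'
#' Manders-type coefficient
#' `r = sum(v1 v2) / sqrt(sum(v1^2) sum(v2^2))`: exactly 1 for perfectly
#' colocalized (proportional) nonnegative signals, 0 for disjoint
#' supports, and invariant to rescaling either input.
#'
#' @param v1,v2 same-shape nonnegative arrays or [opt_volume]s.
#' @param mask optional logical analysis mask (e.g. the retained apical
#'   LV region); when a fitted [lv_ellipsoid] is supplied instead, the
#'   mask is the retained (apical three-quarter) interior of the model.
#' @param voxel_size needed only to build a mask from a model with bare
#'   array input.
#' @return The coefficient, in `[0, 1]` for nonnegative inputs.
#' @export
overlap_coefficient <- function(v1, v2, mask = NULL, voxel_size = NULL) {
  a <- .vol_values(v1); b <- .vol_values(v2)
  .assert(all(dim(a) == dim(b)), "volumes must share shape")
  if (inherits(mask, "lv_ellipsoid")) {
    vs <- voxel_size %||% (if (inherits(v1, "opt_volume")) v1$voxel_size)
    .assert(!is.null(vs), "voxel_size required to build the model mask")
    mask <- .retained_region_mask(mask, dim(a), vs)
  }
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
  }
  sa <- sum(a * a); sb <- sum(b * b)
  .assert(sa > 0 && sb > 0, "overlap coefficient undefined: a volume is all zero")
  sum(a * b) / sqrt(sa * sb)
}

# interior of the model truncated at the base plane (retained apical part)
.retained_region_mask <- function(model, d, voxel_size) {
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  p <- .index_to_mm(idx, d, voxel_size)
  q <- sweep(p, 2, model$center) %*% model$rotation
  a <- model$semi_axes[1]; cc <- model$semi_axes[3]
  z_cut <- cc * (1 - 2 * model$truncation_fraction)
  array((q[, 1]^2 + q[, 2]^2) / a^2 + q[, 3]^2 / cc^2 <= 1 &
          q[, 3] >= z_cut, d)
}

#' Translational cross-correlation function of two probe volumes
#'
#' Computes the overlap coefficient for every integer shift triple
#' `(dx, dy, dz)` up to `max_shift`, on the region where the shifted
#' volumes overlap. The reported shift is the displacement applied to
#' `v2` that maximizes its overlap with `v1`; for colocalized probes the
#' peak sits at zero shift.
#'
#' @param v1,v2 same-shape nonnegative arrays or [opt_volume]s.
#' @param max_shift maximum shift in voxels, scalar or per-axis vector of
#'   3 (>= 1).
#' @param mask optional logical analysis mask (voxels outside it are
#'   ignored in both volumes).
#' @param min_overlap minimum fraction of the volume that must overlap
#'   for a shift to be evaluated (others are NA).
#' @return A `ccf_result`: `r_grid` array over shifts (dimnames = shift
#'   values), `max_r`, `argmax_shift`, plus the inputs' dimensions.
#' @export
ccf_translational <- function(v1, v2, max_shift = 5L, mask = NULL,
                              min_overlap = 0.25) {
  a <- .vol_values(v1); b <- .vol_values(v2)
  .assert(all(dim(a) == dim(b)), "volumes must share shape")
  ms <- rep(as.integer(max_shift), length.out = 3L)
  .assert(all(ms >= 1L), "max_shift must be >= 1 voxel on each axis")
  d <- dim(a)
  .assert(all(ms < d), "max_shift must be smaller than the volume extent")
  if (!is.null(mask)) {
    .assert(all(dim(mask) == d), "mask shape mismatch")
    a <- a * mask; b <- b * mask
  }
  shifts <- lapply(1:3, function(k) seq(-ms[k], ms[k]))
  r_grid <- array(NA_real_, lengths(shifts),
                  dimnames = lapply(shifts, as.character))
  ntot <- prod(d)
  for (ix in seq_along(shifts[[1]])) for (iy in seq_along(shifts[[2]]))
    for (iz in seq_along(shifts[[3]])) {
      s <- c(shifts[[1]][ix], shifts[[2]][iy], shifts[[3]][iz])
      # v2 displaced by s: compare a[x] with b[x - s] on the overlap
      a1 <- pmax(1L, 1L + s); a2 <- pmin(d, d + s)
      if (any(a1 > a2)) next
      if (prod(a2 - a1 + 1L) / ntot < min_overlap) next
      av <- a[a1[1]:a2[1], a1[2]:a2[2], a1[3]:a2[3]]
      bv <- b[(a1[1] - s[1]):(a2[1] - s[1]),
              (a1[2] - s[2]):(a2[2] - s[2]),
              (a1[3] - s[3]):(a2[3] - s[3])]
      sa <- sum(av * av); sb <- sum(bv * bv)
      r_grid[ix, iy, iz] <- if (sa > 0 && sb > 0)
        sum(av * bv) / sqrt(sa * sb) else NA_real_
    }
  best <- which(r_grid == max(r_grid, na.rm = TRUE))[1]
  bi <- arrayInd(best, dim(r_grid))
  argmax <- c(shifts[[1]][bi[1]], shifts[[2]][bi[2]], shifts[[3]][bi[3]])
  structure(list(r_grid = r_grid, shifts = shifts,
                 max_r = r_grid[best], argmax_shift = argmax,
                 dim = d), class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> max r = %.4f at shift (%d, %d, %d) voxels\n",
              x$max_r, x$argmax_shift[1], x$argmax_shift[2],
              x$argmax_shift[3]))
  invisible(x)
}

#' Rotational CCF profiles about the ellipsoid principal axes
#'
#' With `v2` first displaced by the translational CCF argmax, computes
#' the overlap coefficient as a function of rotation angle about each of
#' the model's three principal axes through the model center (trilinear
#' resampling). This is the restricted (translations-first) exploration
#' of the 6-degree-of-freedom alignment.
#'
#' @param v1,v2 same-shape nonnegative arrays or [opt_volume]s.
#' @param model fitted [lv_ellipsoid] providing axes and center.
#' @param ccf a [ccf_translational()] result for the same pair.
#' @param angles_deg symmetric grid of rotation angles, degrees.
#' @param voxel_size mm per voxel (taken from `v1` when an opt_volume).
#' @return list with `angles_deg` and matrix `r` (angles x 3 axes,
#'   columns = local x/y/long axis).
#' @export
ccf_rotational <- function(v1, v2, model, ccf,
                           angles_deg = seq(-20, 20, by = 2),
                           voxel_size = NULL) {
  .assert(length(angles_deg) > 0, "empty angle grid")
  .assert(max(abs(angles_deg + rev(angles_deg))) < 1e-9,
          "angle grid must be symmetric about 0")
  a <- .vol_values(v1); b <- .vol_values(v2)
  vs <- voxel_size %||% (if (inherits(v1, "opt_volume")) v1$voxel_size else 1)
  d <- dim(a)
  s <- ccf$argmax_shift
  b_shift <- .shift3(b, s)
  center_idx <- .mm_to_index(matrix(model$center, 1), d, vs)[1, ]
  r <- matrix(NA_real_, length(angles_deg), 3,
              dimnames = list(NULL, c("x", "y", "long")))
  for (ax in 1:3) {
    axis_world <- model$rotation[, ax]
    for (k in seq_along(angles_deg)) {
      if (angles_deg[k] == 0) {
        br <- b_shift
      } else {
        rot <- .rotation_matrix(axis_world, angles_deg[k])
        br <- .rotate_volume(b_shift, rot, center_idx, outside = 0)
      }
      sa <- sum(a * a); sb <- sum(br * br)
      r[k, ax] <- if (sa > 0 && sb > 0) sum(a * br) / sqrt(sa * sb)
        else NA_real_
    }
  }
  list(angles_deg = angles_deg, r = r, argmax_shift = s)
}

#' Full width at half maximum of a CCF profile
#'
#' Extracts the 1D profile of the translational CCF through its argmax
#' along one axis and measures the linearly interpolated width at half
#' the peak (baseline 0). When the profile never falls below half-max
#' inside the explored shift range, the returned width is the explored
#' span, flagged as a lower bound.
#'
#' @param ccf a [ccf_translational()] result.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Width in voxels; attributes `lower_bound` (logical) and
#'   `profile` (the extracted 1D profile).
#' @export
ccf_fwhm <- function(ccf, axis = 1L) {
  .assert(axis %in% 1:3, "axis must be 1, 2 or 3")
  bi <- vapply(1:3, function(k)
    which(ccf$shifts[[k]] == ccf$argmax_shift[k]), integer(1))
  prof <- switch(axis,
                 ccf$r_grid[, bi[2], bi[3]],
                 ccf$r_grid[bi[1], , bi[3]],
                 ccf$r_grid[bi[1], bi[2], ])
  sh <- ccf$shifts[[axis]]
  pk <- bi[axis]
  half <- prof[pk] / 2
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(pk)) else pk:length(prof)
    p <- prof[idx]
    below <- which(!is.na(p) & p < half)
    if (!length(below)) return(NA_real_)
    j <- below[1]
    # linear interpolation between samples j-1 and j
    x1 <- sh[idx[j - 1]]; x2 <- sh[idx[j]]
    y1 <- p[j - 1]; y2 <- p[j]
    x1 + (half - y1) * (x2 - x1) / (y2 - y1)
  }
  left <- cross(-1); right <- cross(1)
  lb <- is.na(left) || is.na(right)
  width <- if (lb) diff(range(sh)) else abs(right - left)
  structure(width, lower_bound = lb,
            profile = stats::setNames(prof, sh))
}
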