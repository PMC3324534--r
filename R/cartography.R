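# Surface cartography: sampling reconstructed volumes on concentric
# prolate ellipsoid shells and rendering cylindrical and AHA 17-segment
# Bull's-Eye maps; probe-ratio classification; bead-based infarct
# delineation; distance-band probe quantification.

#' Angular grid for surface maps
#'
#' Cell-centered `(mu, theta)` grid: `mu` in `(0, mu_max)` vertically
#' (apex at `mu = 0`), `theta` in `[0, 2 pi)` horizontally and periodic.
#'
#' @param n_mu,n_theta grid resolution.
#' @param mu_max largest polar angle covered (default `pi`, the full
#'   ellipsoid including the non-representative basal region).
#' @return A `map_grid` list with node center vectors `mu`, `theta`.
#' @export
map_grid <- function(n_mu = 60L, n_theta = 120L, mu_max = pi) {
  .assert(n_mu >= 4 && n_theta >= 8, "grid too coarse")
  structure(list(
    n_mu = as.integer(n_mu), n_theta = as.integer(n_theta), mu_max = mu_max,
    mu = (seq_len(n_mu) - 0.5) * mu_max / n_mu,
    theta = (seq_len(n_theta) - 0.5) * 2 * pi / n_theta), class = "map_grid")
}

#' Surface map container
#'
#' A 2D grid of projected signal over the LV surface: cylindrical
#' (`mu` rows x `theta` columns, theta periodic) or a Bull's-Eye raster.
#' Invalid nodes and the basal region above the truncation line are
#' excluded from all quantitative summaries.
#'
#' @param values numeric matrix.
#' @param valid logical matrix, same shape.
#' @param grid the [map_grid()] (cylindrical maps).
#' @param truncation_mu `mu` level of the base cut.
#' @param units free-text units tag.
#' @param kind `"cylindrical"` or `"bullseye"`.
#' @param normalized flag: thickness-normalized values.
#' @return A `surface_map` object.
#' @export
surface_map <- function(values, valid = NULL, grid = NULL,
                        truncation_mu = NULL, units = "",
                        kind = c("cylindrical", "bullseye"),
                        normalized = FALSE) {
  kind <- match.arg(kind)
  valid <- valid %||% !is.na(values)
  .assert(all(dim(values) == dim(valid)), "values/valid shape mismatch")
  structure(list(values = values, valid = valid, grid = grid,
                 truncation_mu = truncation_mu, units = units, kind = kind,
                 normalized = normalized),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map:%s> %d x %d, %d%% valid%s%s\n", x$kind,
              nrow(x$values), ncol(x$values),
              round(100 * mean(x$valid)),
              if (nzchar(x$units)) paste0(", units ", x$units) else "",
              if (x$normalized) ", thickness-normalized" else ""))
  invisible(x)
}

#' @export
plot.surface_map <- function(x, main = NULL, ...) {
  v <- x$values
  v[!x$valid] <- NA
  if (x$kind == "cylindrical") {
    graphics::image(x = x$grid$theta, y = x$grid$mu, z = t(v),
                    xlab = expression(theta), ylab = expression(mu),
                    main = main, ...)
    if (!is.null(x$truncation_mu))
      graphics::abline(h = x$truncation_mu, col = "white", lwd = 2)
  } else {
    graphics::image(z = v, xlab = "", ylab = "", axes = FALSE, asp = 1,
                    main = main, ...)
  }
  invisible(x)
}

# nodes of the retained (sub-truncation) region of a cylindrical map
.retained_nodes <- function(map) {
  keep <- map$valid
  if (!is.null(map$truncation_mu) && !is.null(map$grid))
    keep <- keep & (map$grid$mu <= map$truncation_mu)
  keep
}

#' Sample a volume on concentric prolate ellipsoid shells
#'
#' Trilinear interpolation of the volume at the prolate-frame points of
#' `n_shells` constant-`lam` ellipsoids spanning the myocardial wall from
#' endocardium to epicardium.
#'
#' @param volume an [opt_volume] (its world origin is the grid center).
#' @param model fitted [lv_ellipsoid].
#' @param n_shells number of shells (>= 1), ordered endo -> epi.
#' @param grid a [map_grid()].
#' @param lambda_range numeric `c(lam_endo, lam_epi)`; defaults to the
#'   model's epicardial `lam` and, when the model carries
#'   `endo_semi_axes`, the confocal `lam` matching the endocardial equator
#'   (otherwise 60% of the epicardial value).
#' @return A `shell_samples` object: `values` array
#'   `[n_mu, n_theta, n_shells]`, `valid` array, `lambdas`, `grid`,
#'   `model`.
#' @export
sample_shells <- function(volume, model, n_shells = 10L, grid = map_grid(),
                          lambda_range = NULL) {
  .assert(inherits(volume, "opt_volume"), "`volume` must be opt_volume")
  .assert(n_shells >= 1L, "need n_shells >= 1")
  f <- model$focal_distance
  .assert(is.finite(f), "model has no defined focal distance")
  if (is.null(lambda_range)) {
    lam_epi <- .lam_of_model(model)
    lam_endo <- if (!is.null(model$endo_semi_axes))
      asinh(mean(model$endo_semi_axes[1:2]) / f) else 0.6 * lam_epi
    lambda_range <- c(lam_endo, lam_epi)
  }
  lambdas <- if (n_shells == 1L) mean(lambda_range) else
    seq(lambda_range[1], lambda_range[2], length.out = n_shells)
  d <- dim(volume$values)
  nn <- grid$n_mu * grid$n_theta
  nodes <- cbind(mu = rep(grid$mu, times = grid$n_theta),
                 theta = rep(grid$theta, each = grid$n_mu))
  values <- array(NA_real_, c(grid$n_mu, grid$n_theta, n_shells))
  pos_first <- pos_last <- NULL
  for (s in seq_len(n_shells)) {
    pts <- prolate_to_cartesian(cbind(lambdas[s], nodes), model)
    if (s == 1L) pos_first <- pts
    if (s == n_shells) pos_last <- pts
    idx <- .mm_to_index(pts, d, volume$voxel_size)
    values[, , s] <- matrix(.trilinear(volume$values, idx),
                            grid$n_mu, grid$n_theta)
  }
  # radial extent spanned by the shells at each node (mm)
  radial_span <- matrix(sqrt(rowSums((pos_last - pos_first)^2)),
                        grid$n_mu, grid$n_theta)
  structure(list(values = values, valid = !is.na(values),
                 lambdas = lambdas, radial_span = radial_span,
                 grid = grid, model = model),
            class = "shell_samples")
}

#' @export
print.shell_samples <- function(x, ...) {
  cat(sprintf("<shell_samples> %d shells, lam [%.3f, %.3f], grid %d x %d\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              x$grid$n_mu, x$grid$n_theta))
  invisible(x)
}

#' 2D total projection of shell samples
#'
#' Sums the signal across shells at every angular node (the integral
#' along the ellipsoid's radial direction); optionally divides by the
#' local wall thickness so fluorescence maps are independent of the
#' myocardial thickness traversed.
#'
#' @param shells a [sample_shells()] result.
#' @param thickness_map [surface_map] of wall thickness on the same grid
#'   (required when `normalize = TRUE`).
#' @param normalize divide by local thickness. The shell sum is first
#'   scaled by the per-node radial step (shell span / shell count) so it
#'   approximates the true radial line integral; dividing that by the
#'   wall thickness yields a mean concentration that is independent of
#'   how much myocardium the radial ray traverses (a uniform field maps
#'   to a constant).
#' @return A cylindrical [surface_map]; nodes with any invalid shell
#'   sample, and (when normalizing) zero thickness, are invalid.
#' @export
total_projection <- function(shells, thickness_map = NULL,
                             normalize = FALSE) {
  .assert(inherits(shells, "shell_samples"), "`shells` must be shell_samples")
  vals <- apply(shells$values, c(1, 2), sum)
  valid <- apply(shells$valid, c(1, 2), all)
  units <- "sum over shells"
  if (normalize) {
    .assert(!is.null(thickness_map), "normalize = TRUE needs a thickness map")
    .assert(all(dim(thickness_map$values) == dim(vals)),
            "thickness map grid mismatch")
    n_sh <- dim(shells$values)[3]
    step <- if (n_sh > 1L) shells$radial_span / n_sh else 1
    th <- thickness_map$values
    ok <- thickness_map$valid & !is.na(th) & th > 0
    vals <- ifelse(ok, vals * step / th, NA_real_)
    valid <- valid & ok
    units <- "per mm thickness"
  }
  surface_map(vals, valid = valid, grid = shells$grid,
              truncation_mu = truncation_mu(shells$model), units = units,
              kind = "cylindrical", normalized = normalize)
}

#' Bull's-Eye rendering of a cylindrical map
#'
#' Polar re-gridding of a cylindrical map onto a disk raster: radius
#' proportional to `mu` (apex at the center, truncation line at the rim),
#' polar angle equal to `theta`. Values are bilinearly interpolated with
#' periodic `theta`; because radius is linear in `mu`, the disk area
#' element matches `mu dmu dtheta` and area-weighted totals are preserved
#' up to interpolation error.
#'
#' @param map cylindrical [surface_map].
#' @param n_pixels raster side length (odd recommended).
#' @return A [surface_map] of kind `"bullseye"`; pixels outside the disk
#'   are invalid.
#' @export
bulls_eye <- function(map, n_pixels = 201L) {
  .assert(inherits(map, "surface_map") && map$kind == "cylindrical",
          "`map` must be a cylindrical surface_map")
  g <- map$grid
  mu_rim <- map$truncation_mu %||% g$mu_max
  xy <- seq(-1, 1, length.out = n_pixels)
  xm <- matrix(xy, n_pixels, n_pixels)
  ym <- matrix(xy, n_pixels, n_pixels, byrow = TRUE)
  r <- sqrt(xm^2 + ym^2)
  th <- atan2(ym, xm) %% (2 * pi)
  mu <- r * mu_rim
  inside <- r <= 1
  # fractional indices on the cell-centered cylindrical grid
  iu <- mu / (g$mu_max / g$n_mu) + 0.5
  jt <- th / (2 * pi / g$n_theta) + 0.5
  # periodic theta: pad one wrapped column on each side
  vv <- map$values
  vv[!map$valid] <- NA
  vpad <- cbind(vv[, g$n_theta], vv, vv[, 1])
  jt <- jt + 1
  i0 <- pmin(pmax(floor(iu), 1), g$n_mu - 1)
  j0 <- pmin(pmax(floor(jt), 1), g$n_theta + 1)
  fi <- pmin(pmax(iu - i0, 0), 1)
  fj <- pmin(pmax(jt - j0, 0), 1)
  gidx <- function(i, j) vpad[cbind(as.vector(i), as.vector(j))]
  val <- (1 - fi) * (1 - fj) * gidx(i0, j0) + fi * (1 - fj) * gidx(i0 + 1, j0) +
    (1 - fi) * fj * gidx(i0, j0 + 1) + fi * fj * gidx(i0 + 1, j0 + 1)
  val <- matrix(val, n_pixels, n_pixels)
  val[!inside] <- NA
  surface_map(val, valid = inside & !is.na(val), grid = NULL,
              truncation_mu = mu_rim, units = map$units, kind = "bullseye",
              normalized = map$normalized)
}

#' AHA 17-segment labels on a cylindrical grid
#'
#' Standardized American Heart Association partition of the retained
#' (apical three-quarter) region: three `mu` rings of equal width with 6
#' basal (1-6) and 6 mid-cavity (7-12) sectors at 60 degrees, 4 apical
#' sectors (13-16) at 90 degrees (rotated 45 degrees, per convention),
#' and the apical cap (17) as the inner half of the apical ring. Nodes
#' above the truncation line are `NA`.
#'
#' @param map a cylindrical [surface_map], or a [map_grid()] together
#'   with `truncation_mu`.
#' @param truncation_mu base-cut `mu` (taken from the map when omitted).
#' @param theta_offset azimuthal origin of the anterior wall, radians.
#' @return Integer matrix of labels 1..17 (`NA` beyond the truncation
#'   line) with attribute `boundaries` (the ring `mu` cut points).
#' @export
aha17_labels <- function(map, truncation_mu = NULL, theta_offset = 0) {
  if (inherits(map, "surface_map")) {
    g <- map$grid
    truncation_mu <- truncation_mu %||% map$truncation_mu
  } else {
    g <- map
  }
  .assert(inherits(g, "map_grid"), "need a cylindrical map or map_grid")
  .assert(!is.null(truncation_mu), "truncation line undefined")
  mu <- g$mu; th <- (g$theta - theta_offset) %% (2 * pi)
  t3 <- truncation_mu / 3
  lab <- matrix(NA_integer_, g$n_mu, g$n_theta)
  sector6 <- function(theta) 1L + (floor(theta / (pi / 3)) %% 6L)
  sector4 <- function(theta) 1L + (floor((theta - pi / 4) %% (2 * pi) /
                                           (pi / 2)) %% 4L)
  for (i in seq_len(g$n_mu)) {
    if (mu[i] > truncation_mu) next
    lab[i, ] <- if (mu[i] >= 2 * t3) {            # basal ring: 1-6
      sector6(th)
    } else if (mu[i] >= t3) {                     # mid-cavity: 7-12
      6L + sector6(th)
    } else if (mu[i] >= t3 / 2) {                 # apical ring: 13-16
      12L + sector4(th)
    } else 17L                                    # apical cap
  }
  attr(lab, "boundaries") <- c(cap = t3 / 2, apical = t3, mid = 2 * t3,
                               basal = truncation_mu)
  lab
}

#' Per-segment summary of a cylindrical map
#'
#' @param map cylindrical [surface_map].
#' @param labels result of [aha17_labels()] (computed when NULL).
#' @return data.frame with segment id, node count and area-weighted mean
#'   (weights `sin(mu)`, the surface area element), invalid nodes
#'   excluded.
#' @export
aha17_segment_stats <- function(map, labels = NULL) {
  labels <- labels %||% aha17_labels(map)
  w <- matrix(sin(map$grid$mu), map$grid$n_mu, map$grid$n_theta)
  keep <- map$valid & !is.na(labels)
  df <- data.frame(segment = 1:17, n = NA_integer_, mean = NA_real_)
  for (s in 1:17) {
    sel <- keep & labels == s
    df$n[s] <- sum(sel)
    df$mean[s] <- if (any(sel))
      sum(map$values[sel] * w[sel]) / sum(w[sel]) else NA_real_
  }
  df
}

#' Classify the ratio of two co-registered maps
#'
#' Pixelwise ratio `a / b` against thresholds: above `hi` is `"high"`
#' (the inflammatory regime when `a` is the protease and `b` the
#' phagocyte channel), within `[lo, hi]` `"intermediate"`, below `lo`
#' `"low"`; nodes where `b` falls below a floor are `"undefined"` and
#' excluded from any area statistic. Scale-invariant: rescaling both maps
#' by one positive constant leaves all labels unchanged.
#'
#' @param map_a,map_b co-registered [surface_map]s (identical grids).
#' @param hi,lo thresholds, `hi > lo > 0` (defaults 1.1 and 0.9).
#' @param floor_frac denominator floor as a fraction of the maximum of
#'   `map_b` over its valid nodes.
#' @return Character matrix with levels high/intermediate/low/undefined,
#'   attribute `ratio` (the raw ratio matrix, NA where undefined).
#' @export
ratio_classify <- function(map_a, map_b, hi = 1.1, lo = 0.9,
                           floor_frac = 1e-3) {
  .assert(all(dim(map_a$values) == dim(map_b$values)),
          "maps are not on the same grid")
  .assert(hi > lo && lo > 0, "need hi > lo > 0")
  a <- map_a$values; b <- map_b$values
  floor_b <- floor_frac * max(b[map_b$valid], na.rm = TRUE)
  ok <- map_a$valid & map_b$valid & !is.na(a) & !is.na(b) & b > floor_b
  ratio <- ifelse(ok, a / b, NA_real_)
  out <- matrix("undefined", nrow(a), ncol(a))
  out[ok & ratio > hi] <- "high"
  out[ok & ratio <= hi & ratio >= lo] <- "intermediate"
  out[ok & ratio < lo] <- "low"
  attr(out, "ratio") <- ratio
  attr(out, "thresholds") <- c(lo = lo, hi = hi)
  out
}

#' Delineate the infarct from the perfusion-bead channel
#'
#' Microbeads injected before harvest perfuse the whole myocardium except
#' the non-perfused infarct: the infarct is recovered as the myocardial
#' voxels with bead signal below threshold, morphologically closed, with
#' the largest connected component retained.
#'
#' @param bead_volume reconstructed bead [opt_volume] (or bare array).
#' @param myocardium_mask logical 3D array.
#' @param method `"otsu"` (threshold on the myocardial bead histogram) or
#'   `"fraction"` (a fraction of the myocardial median).
#' @param fraction threshold fraction for `method = "fraction"`.
#' @param closing_radius morphological closing radius, voxels.
#' @return Logical 3D array; attribute `empty` is TRUE (with an empty
#'   mask) when the bead signal shows no hypoperfused region.
#' @export
infarct_mask_from_beads <- function(bead_volume, myocardium_mask,
                                    method = c("otsu", "fraction"),
                                    fraction = 0.5, closing_radius = 2L) {
  method <- match.arg(method)
  b <- .vol_values(bead_volume)
  .assert(all(dim(b) == dim(myocardium_mask)), "shape mismatch")
  vals <- b[myocardium_mask]
  .assert(any(vals > 0), "cannot delineate: bead volume is all zero")
  rng <- range(vals)
  if (diff(rng) < 1e-9 * max(abs(rng))) {
    out <- array(FALSE, dim(b))
    attr(out, "empty") <- TRUE
    return(out)
  }
  thr <- switch(method,
    otsu = {
      x01 <- matrix((vals - rng[1]) / diff(rng), ncol = 1)
      rng[1] + EBImage::otsu(x01, range = c(0, 1)) * diff(rng)
    },
    fraction = fraction * stats::median(vals))
  cand <- myocardium_mask & b < thr
  if (!any(cand)) {
    attr(cand, "empty") <- TRUE
    return(cand)
  }
  cand <- .close6(cand, closing_radius) & myocardium_mask
  out <- .largest_component(cand)
  attr(out, "empty") <- !any(out)
  out
}

#' Probe density in distance bands around the infarct
#'
#' Euclidean-distance-transform bands from the infarct boundary,
#' restricted to the myocardium outside the infarct: per band, total
#' probe signal divided by band volume (per mm^3). Also reports the
#' remote fraction: the share of the total myocardial signal lying
#' outside every band (and outside the infarct), the quantity behind
#' remote-recruitment estimates.
#'
#' @param probe_volume reconstructed probe [opt_volume] or bare array.
#' @param infarct_mask,myocardium_mask logical 3D arrays.
#' @param bands_mm list of disjoint `c(min, max)` distance intervals in
#'   mm (default `list(c(1, 3), c(4, 6))`).
#' @param voxel_size voxel edge, mm (taken from an opt_volume input).
#' @return data.frame with one row per band (`d_lo`, `d_hi`,
#'   `volume_mm3`, `signal`, `density`, `empty` flag); attributes
#'   `remote_fraction` and `total_signal`.
#' @export
distance_band_density <- function(probe_volume, infarct_mask,
                                  myocardium_mask,
                                  bands_mm = list(c(1, 3), c(4, 6)),
                                  voxel_size = NULL) {
  p <- .vol_values(probe_volume)
  if (inherits(probe_volume, "opt_volume"))
    voxel_size <- voxel_size %||% probe_volume$voxel_size
  .assert(!is.null(voxel_size), "voxel_size required for bare arrays")
  .assert(all(dim(p) == dim(infarct_mask)) &&
            all(dim(p) == dim(myocardium_mask)), "shape mismatch")
  lim <- vapply(bands_mm, range, numeric(2))
  .assert(all(lim[1, ] < lim[2, ]), "bands must be [min, max) with min < max")
  region <- myocardium_mask & !infarct_mask
  if (!any(region)) {
    out <- data.frame(d_lo = lim[1, ], d_hi = lim[2, ], volume_mm3 = 0,
                      signal = NA_real_, density = NA_real_, empty = TRUE)
    attr(out, "remote_fraction") <- NA_real_
    warning("distance_band_density: no myocardium outside the infarct")
    return(out)
  }
  dmap <- .edt3(infarct_mask, voxel_size)
  in_any <- array(FALSE, dim(p))
  out <- data.frame(d_lo = lim[1, ], d_hi = lim[2, ], volume_mm3 = NA_real_,
                    signal = NA_real_, density = NA_real_, empty = FALSE)
  for (k in seq_along(bands_mm)) {
    sel <- region & dmap >= lim[1, k] & dmap < lim[2, k]
    in_any <- in_any | sel
    nv <- sum(sel)
    out$volume_mm3[k] <- nv * voxel_size^3
    out$empty[k] <- nv == 0L
    out$signal[k] <- if (nv) sum(p[sel]) else NA_real_
    out$density[k] <- if (nv) out$signal[k] / out$volume_mm3[k] else NA_real_
  }
  total <- sum(p[myocardium_mask])
  attr(out, "total_signal") <- total
  attr(out, "remote_fraction") <-
    if (total > 0) sum(p[region & !in_any]) / total else NA_real_
  out
}
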