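#' Synthetic left-ventricle OPT phantom
#'
#' Builds a digital mouse-heart phantom: the left-ventricular myocardium is
#' the region between two concentric coaxial ellipsoids, truncated at a base
#' plane so that `truncation_fraction` of the long-axis extent is retained
#' from the apex. A wedge-shaped non-perfused infarct is carved into the
#' myocardium; two fluorescent probe fields concentrate in and around the
#' infarct with a configurable peri-infarct/remote contrast; perfusion beads
#' fill the myocardium homogeneously except inside the infarct; an
#' absorption map gives the myocardium realistic optical attenuation.
#'
#' World coordinates are mm with the origin at the grid center; the phantom
#' long axis is the local z axis of `rotation`, apex pointing towards local
#' +z.
#'
#' @param grid_shape integer vector of 3 (>= 32 each), voxel grid size.
#' @param voxel_size isotropic voxel edge, mm.
#' @param epi_semi_axes,endo_semi_axes epicardial and endocardial ellipsoid
#'   semi-axes `c(a, b, c)` in mm, `c` along the long axis. Every
#'   endocardial semi-axis must be strictly smaller than its epicardial
#'   counterpart.
#' @param center ellipsoid center in mm (world frame).
#' @param rotation 3x3 orthonormal matrix mapping local to world axes.
#' @param truncation_fraction fraction of the long-axis extent (2c)
#'   retained from the apex; the basal remainder is cut away.
#' @param infarct_params list with `theta_deg` (azimuth range, degrees) and
#'   `z_min_frac` (lower bound of local z as a fraction of c): the infarct
#'   wedge is the myocardium inside this azimuth range and above this
#'   level (towards the apex).
#' @param probe_contrast peri-infarct/remote density ratio of the probe
#'   fields (1 = uniform over the myocardium).
#' @param probe_halo_mm Gaussian length scale (mm) of the peri-infarct halo
#'   (ignored for `probe_profile = "bands"`).
#' @param probe_profile `"halo"` for a smooth distance-weighted halo,
#'   `"bands"` for a piecewise-constant profile: `probe_contrast` times the
#'   remote level at infarct-boundary distances below `bands_break_mm`, the
#'   remote level beyond.
#' @param bands_break_mm distance break (mm) of the `"bands"` profile.
#' @param absorption list: `background`, `myocardium`, `cavity` attenuation
#'   coefficients (1/mm) and `heterogeneity`, the relative amplitude of a
#'   smooth random attenuation modulation inside the myocardium.
#' @param bead_level bead density inside the perfused myocardium.
#' @param seed integer seed fixing all randomness.
#' @return An object of class `phantom_scene`: opt_volume fields
#'   `absorption`, `probe_a`, `probe_b`, `beads`, logical arrays `lv_mask`,
#'   `myocardium_mask`, `infarct_mask`, the ground-truth [lv_ellipsoid]
#'   `true_ellipsoid` (with the endocardial semi-axes attached as
#'   `endo_semi_axes`), and `voxel_size`.
#' @examples
#' ph <- make_lv_phantom(grid_shape = c(48, 48, 48), voxel_size = 0.25)
#' sum(ph$infarct_mask) > 0
#' @export
make_lv_phantom <- function(grid_shape = c(96, 96, 96),
                            voxel_size = 0.12,
                            epi_semi_axes = c(3.0, 3.0, 4.6),
                            endo_semi_axes = c(2.2, 2.2, 3.8),
                            center = c(0, 0, 0),
                            rotation = diag(3),
                            truncation_fraction = 0.75,
                            infarct_params = list(theta_deg = c(20, 140),
                                                  z_min_frac = -0.1),
                            probe_contrast = 4,
                            probe_halo_mm = 1.5,
                            probe_profile = c("halo", "bands"),
                            bands_break_mm = 3.5,
                            absorption = list(background = 0.01,
                                              myocardium = 0.25,
                                              cavity = 0.02,
                                              heterogeneity = 0),
                            bead_level = 1,
                            seed = 1L) {
  probe_profile <- match.arg(probe_profile)
  .assert(all(grid_shape >= 32L), "grid_shape must be at least 32 per axis")
  .assert(all(endo_semi_axes > 0) && all(epi_semi_axes > endo_semi_axes),
          "invalid geometry: need epicardial semi-axes > endocardial semi-axes > 0")
  .assert(truncation_fraction > 0 && truncation_fraction <= 1,
          "truncation_fraction must lie in (0, 1]")
  set.seed(seed)

  d <- as.integer(grid_shape)
  # world mm coordinates of voxel centers, origin at grid center
  ax <- lapply(1:3, function(k) (seq_len(d[k]) - (d[k] + 1) / 2) * voxel_size)
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  # local frame coordinates
  q <- sweep(g, 2, center) %*% rotation  # rows = R^T (p - center)
  a_e <- epi_semi_axes; a_i <- endo_semi_axes
  z_cut <- a_e[3] * (1 - 2 * truncation_fraction)

  inside_epi <- (q[, 1] / a_e[1])^2 + (q[, 2] / a_e[2])^2 +
    (q[, 3] / a_e[3])^2 <= 1
  inside_endo <- (q[, 1] / a_i[1])^2 + (q[, 2] / a_i[2])^2 +
    (q[, 3] / a_i[3])^2 <= 1
  retained <- q[, 3] >= z_cut
  lv_mask <- array(inside_epi & retained, d)
  myocardium <- array(inside_epi & !inside_endo & retained, d)
  cavity <- array(inside_endo & retained, d)

  theta <- atan2(q[, 2], q[, 1]) * 180 / pi  # (-180, 180]
  th <- infarct_params$theta_deg %||% c(20, 140)
  zmin <- (infarct_params$z_min_frac %||% -0.1) * a_e[3]
  in_wedge <- theta >= th[1] & theta <= th[2] & q[, 3] >= zmin
  infarct <- myocardium & array(in_wedge, d)
  .assert(sum(infarct) > 0,
          "invalid geometry: infarct wedge does not intersect the myocardium")

  # distance (mm) from the infarct, 0 inside it
  d_inf <- .edt3(infarct, voxel_size)

  halo_weight <- switch(probe_profile,
    halo  = exp(-d_inf^2 / (2 * probe_halo_mm^2)),
    bands = as.numeric(d_inf < bands_break_mm))
  probe_a <- array(0, d)
  probe_a[myocardium] <- 1 + (probe_contrast - 1) * halo_weight[myocardium]
  probe_b <- array(0, d)
  hw_b <- switch(probe_profile,
    halo  = exp(-d_inf^2 / (2 * (1.3 * probe_halo_mm)^2)),
    bands = as.numeric(d_inf < bands_break_mm))
  contrast_b <- if (probe_contrast == 1) 1 else 1 + 0.8 * (probe_contrast - 1)
  probe_b[myocardium] <- 1 + (contrast_b - 1) * hw_b[myocardium]

  beads <- array(0, d)
  beads[myocardium & !infarct] <- bead_level

  mu <- array(absorption$background %||% 0.01, d)
  mu[myocardium] <- absorption$myocardium %||% 0.25
  mu[cavity] <- absorption$cavity %||% 0.02
  het <- absorption$heterogeneity %||% 0
  if (het > 0) {
    field <- .smooth_field(d, n_coarse = 6L)
    mu[myocardium] <- mu[myocardium] * pmax(0.2, 1 + het * field[myocardium])
  }

  model <- lv_ellipsoid(center = center, rotation = rotation,
                        semi_axes = a_e,
                        truncation_fraction = truncation_fraction)
  model$endo_semi_axes <- a_i

  structure(list(
    absorption = opt_volume(mu, voxel_size, channel = "absorption"),
    probe_a = opt_volume(probe_a, voxel_size, channel = "probe_a"),
    probe_b = opt_volume(probe_b, voxel_size, channel = "probe_b"),
    beads = opt_volume(beads, voxel_size, channel = "beads"),
    lv_mask = lv_mask, myocardium_mask = myocardium, infarct_mask = infarct,
    true_ellipsoid = model, voxel_size = voxel_size, seed = seed
  ), class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  d <- dim(x$lv_mask)
  cat(sprintf("<phantom_scene> %d x %d x %d @ %g mm\n", d[1], d[2], d[3],
              x$voxel_size))
  cat(sprintf("  myocardium %d voxels, infarct %d voxels\n",
              sum(x$myocardium_mask), sum(x$infarct_mask)))
  invisible(x)
}

# smooth unit-variance random field: coarse white noise upsampled trilinearly
.smooth_field <- function(d, n_coarse = 6L) {
  coarse <- array(stats::rnorm(n_coarse^3), rep(n_coarse, 3L))
  g <- as.matrix(expand.grid(
    x = seq(1, n_coarse, length.out = d[1]),
    y = seq(1, n_coarse, length.out = d[2]),
    z = seq(1, n_coarse, length.out = d[3])))
  f <- array(.trilinear(coarse, g), d)
  f / stats::sd(f)
}

## ---- forward model ----

# Bilinear gather weights for sampling a d1 x d2 slice rotated by theta:
# output (x', y') samples source (x' cos - y' sin, x' sin + y' cos)
# (centered coordinates). Returns clamped base indices and weights with
# out-of-grid samples given zero weight.
.rot_gather <- function(d1, d2, theta_deg) {
  th <- theta_deg * pi / 180
  cx <- (d1 + 1) / 2; cy <- (d2 + 1) / 2
  xp <- rep(seq_len(d1) - cx, times = d2)
  yp <- rep(seq_len(d2) - cy, each = d1)
  xs <- xp * cos(th) - yp * sin(th) + cx
  ys <- xp * sin(th) + yp * cos(th) + cy
  inside <- xs >= 1 & xs <= d1 & ys >= 1 & ys <= d2
  x0 <- pmin(pmax(floor(xs), 1L), d1 - 1L)
  y0 <- pmin(pmax(floor(ys), 1L), d2 - 1L)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  base <- x0 + (y0 - 1L) * d1
  list(base = base, d1 = d1,
       w00 = (1 - fx) * (1 - fy) * inside, w10 = fx * (1 - fy) * inside,
       w01 = (1 - fx) * fy * inside,       w11 = fx * fy * inside)
}

# apply gather to a (d1*d2) x n matrix of flattened slices
.rot_apply <- function(gth, m) {
  b <- gth$base
  gth$w00 * m[b, , drop = FALSE] + gth$w10 * m[b + 1L, , drop = FALSE] +
    gth$w01 * m[b + gth$d1, , drop = FALSE] +
    gth$w11 * m[b + gth$d1 + 1L, , drop = FALSE]
}

# sum over y' (dim 2) of a d1 x d2 x nz array given as flat matrix
.ray_sums <- function(flat, d1, d2, nz) {
  colSums(aperm(array(flat, c(d1, d2, nz)), c(2, 1, 3)))  # d1 x nz
}

.cumsum_dim2 <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(2, 1, 3)), d[2], d[1] * d[3])
  m <- apply(m, 2, cumsum)
  aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Simulate parallel-beam OPT projections
#'
#' Forward-projects a volume with a telecentric parallel-beam geometry
#' rotating about the z axis. In `"transmission"` mode the volume is an
#' attenuation-coefficient map (1/mm) and frames follow Beer-Lambert:
#' `I = I0 exp(-line integral of mu)`. In `"fluorescence"` mode the volume
#' is a fluorophore density and each frame is the single-scatter
#' (Born-type) attenuated line integral: the emission of every voxel is
#' attenuated by the absorption integral along the collimated illumination
#' path up to the voxel and along the detection path from the voxel to the
#' detector.
#'
#' @param volume [opt_volume] (or bare 3D array with `voxel_size` given):
#'   attenuation map (transmission) or fluorophore density (fluorescence).
#' @param angles projection angles, degrees, strictly increasing.
#' @param mode `"transmission"` or `"fluorescence"`.
#' @param absorption attenuation-coefficient [opt_volume] required in
#'   fluorescence mode (excitation wavelength).
#' @param absorption_em optional distinct emission-wavelength attenuation
#'   map; defaults to `absorption` (same spectral band), in which case a
#'   fast path is used (the excitation plus detection path integrals then
#'   sum to the full chord through the sample).
#' @param I0 source intensity for transmission mode.
#' @param voxel_size required if `volume` is a bare array.
#' @return An [opt_projections] stack, frames indexed
#'   `[detector column, detector row (z), angle]`.
#' @examples
#' ph <- make_lv_phantom(grid_shape = c(32, 32, 32), voxel_size = 0.3)
#' pr <- forward_project(ph$absorption, angles = seq(0, 179, by = 12))
#' range(pr$frames)
#' @export
forward_project <- function(volume, angles,
                            mode = c("transmission", "fluorescence"),
                            absorption = NULL, absorption_em = NULL,
                            I0 = 1, voxel_size = NULL) {
  mode <- match.arg(mode)
  vs <- if (inherits(volume, "opt_volume")) volume$voxel_size else voxel_size
  .assert(!is.null(vs), "voxel_size must be supplied for bare arrays")
  v <- .vol_values(volume)
  d <- dim(v)
  .assert(d[1] == d[2], "axial slices must be square (nx == ny)")
  .assert(all(diff(angles) > 0), "`angles` must be strictly increasing")
  nz <- d[3]
  npix <- d[1] * d[2]
  if (mode == "transmission") {
    .assert(min(v) >= 0, "negative absorption coefficients are not allowed")
    mu_m <- matrix(v, npix, nz)
    frames <- array(0, c(d[1], nz, length(angles)))
    for (k in seq_along(angles)) {
      gth <- .rot_gather(d[1], d[2], angles[k])
      chord <- .ray_sums(.rot_apply(gth, mu_m), d[1], d[2], nz) * vs
      frames[, , k] <- I0 * exp(-chord)
    }
    return(opt_projections(frames, angles, channel = "transmission", I0 = I0))
  }
  .assert(!is.null(absorption), "fluorescence mode requires an absorption map")
  mu <- .vol_values(absorption)
  .assert(all(dim(mu) == d), "absorption and fluorophore volumes must share shape")
  .assert(min(mu) >= 0, "negative absorption coefficients are not allowed")
  .assert(min(v) >= 0, "fluorophore density must be nonnegative")
  same_band <- is.null(absorption_em)
  mu_em <- if (same_band) mu else .vol_values(absorption_em)
  .assert(all(dim(mu_em) == d), "emission absorption map must share shape")
  f_m <- matrix(v, npix, nz)
  mu_m <- matrix(mu, npix, nz)
  mue_m <- matrix(mu_em, npix, nz)
  frames <- array(0, c(d[1], nz, length(angles)))
  for (k in seq_along(angles)) {
    gth <- .rot_gather(d[1], d[2], angles[k])
    f_rot <- .rot_apply(gth, f_m)
    if (same_band) {
      # excitation + detection path integrals sum to the full chord
      chord <- .ray_sums(.rot_apply(gth, mu_m), d[1], d[2], nz) * vs
      frames[, , k] <- exp(-chord) * .ray_sums(f_rot, d[1], d[2], nz) * vs
    } else {
      mu_rot <- array(.rot_apply(gth, mu_m), c(d[1], d[2], nz))
      mue_rot <- array(.rot_apply(gth, mue_m), c(d[1], d[2], nz))
      f_arr <- array(f_rot, c(d[1], d[2], nz))
      a_ex <- (.cumsum_dim2(mu_rot) - mu_rot / 2) * vs
      rev_idx <- rev(seq_len(d[2]))
      a_em <- (.cumsum_dim2(mue_rot[, rev_idx, , drop = FALSE])[, rev_idx, ,
                                                                drop = FALSE] -
                 mue_rot / 2) * vs
      att <- f_arr * exp(-(a_ex + a_em))
      frames[, , k] <- colSums(aperm(att, c(2, 1, 3))) * vs
    }
  }
  opt_projections(frames, angles, channel = "fluorescence", I0 = I0)
}

#' Artifact configuration for simulated acquisitions
#'
#' @param source_fluctuation_sd relative SD of the per-angle source power
#'   factor (log-normal, mean ~1): lamp flicker, visible as vertical
#'   sinogram stripes.
#' @param detector_gain_sd relative SD of the fixed per-detector-column
#'   gain: CCD non-uniformity, the origin of reconstruction ring artifacts.
#' @param noise_model `"none"`, `"gaussian"` (additive) or `"poisson"`
#'   (shot noise).
#' @param noise_scale gaussian: SD as a fraction of `I0`; poisson: photon
#'   counts per intensity unit.
#' @param seed integer; fixes all randomness.
#' @return An `artifact_config` list.
#' @export
artifact_config <- function(source_fluctuation_sd = 0, detector_gain_sd = 0,
                            noise_model = c("none", "gaussian", "poisson"),
                            noise_scale = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  .assert(source_fluctuation_sd >= 0 && is.finite(source_fluctuation_sd),
          "source_fluctuation_sd must be finite and >= 0")
  .assert(detector_gain_sd >= 0 && is.finite(detector_gain_sd),
          "detector_gain_sd must be finite and >= 0")
  structure(list(source_fluctuation_sd = source_fluctuation_sd,
                 detector_gain_sd = detector_gain_sd,
                 noise_model = noise_model, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "artifact_config")
}

#' Inject instrument artifacts into a projection stack
#'
#' Multiplies every frame by a per-angle random source-power factor,
#' every detector column by a fixed per-column gain, and adds noise. The
#' clean frames and the drawn factors are retained on the result for
#' oracle comparisons.
#'
#' @param proj an [opt_projections] stack.
#' @param config an [artifact_config].
#' @return An [opt_projections] with extra fields `clean` (input frames),
#'   `source_factors` (per angle) and `column_gains` (per detector column).
#' @export
inject_artifacts <- function(proj, config) {
  .assert(inherits(proj, "opt_projections"), "`proj` must be opt_projections")
  .assert(inherits(config, "artifact_config"), "`config` must be artifact_config")
  set.seed(config$seed)
  d <- dim(proj$frames)
  sf <- if (config$source_fluctuation_sd > 0)
    exp(stats::rnorm(d[3], 0, config$source_fluctuation_sd)) else rep(1, d[3])
  cg <- if (config$detector_gain_sd > 0)
    1 + stats::rnorm(d[1], 0, config$detector_gain_sd) else rep(1, d[1])
  frames <- proj$frames *
    rep(sf, each = d[1] * d[2]) *  # per-angle source factor
    cg                              # per-column gain, recycled along dim 1
  if (config$noise_model == "gaussian" && config$noise_scale > 0) {
    frames <- frames + stats::rnorm(length(frames), 0,
                                    config$noise_scale * proj$I0)
    frames <- pmax(frames, 1e-6 * proj$I0)
  } else if (config$noise_model == "poisson" && config$noise_scale > 0) {
    frames <- array(stats::rpois(length(frames),
                                 pmax(frames, 0) * config$noise_scale) /
                      config$noise_scale, d)
    frames <- pmax(frames, 1e-6 * proj$I0)
  }
  out <- opt_projections(array(frames, d), proj$angles,
                         channel = proj$channel, I0 = proj$I0)
  out$clean <- proj$frames
  out$source_factors <- sf
  out$column_gains <- cg
  out
}
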