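make_test_model <- function() lv_ellipsoid(c(0, 0, 0), diag(3), c(3, 3, 4.6))

test_that("shell sampling reproduces constant and axisymmetric fields", {
  m <- make_test_model()
  n <- 64; vox <- 0.2
  g <- map_grid(24, 48)
  const <- opt_volume(array(2.5, c(n, n, n)), vox)
  sh <- sample_shells(const, m, n_shells = 5, grid = g)
  expect_true(all(sh$valid))
  expect_equal(max(abs(sh$values - 2.5)), 0)

  # field linear in z: maps depend on mu only (axisymmetric)
  zl <- array(rep((1:n) - (n + 1) / 2, each = n * n) * vox, c(n, n, n))
  shz <- sample_shells(opt_volume(zl, vox), m, n_shells = 3, grid = g)
  col_var <- apply(shz$values[, , 2], 1, stats::var)
  expect_lt(max(col_var), 1e-18)

  # single epicardial shell equals the analytic surface values
  sh1 <- sample_shells(opt_volume(zl, vox), m, n_shells = 1, grid = g,
                       lambda_range = rep(optheart:::.lam_of_model(m), 2))
  f <- m$focal_distance
  want <- outer(f * cosh(optheart:::.lam_of_model(m)) * cos(g$mu),
                rep(1, g$n_theta))
  expect_equal(sh1$values[, , 1], want, tolerance = 1e-10)

  # shells exiting the volume are invalid, not extrapolated
  tiny <- opt_volume(array(1, c(16, 16, 16)), 0.1)
  sh_out <- sample_shells(tiny, m, n_shells = 2, grid = g)
  expect_true(any(!sh_out$valid))
})

test_that("total projection sums shells and normalizes by thickness", {
  m <- make_test_model()
  n <- 64; vox <- 0.2
  g <- map_grid(24, 48)
  unit <- opt_volume(array(1, c(n, n, n)), vox)
  sh <- sample_shells(unit, m, n_shells = 6, grid = g)
  tp <- total_projection(sh)
  expect_equal(max(abs(tp$values - 6)), 0)

  sh1 <- sample_shells(unit, m, n_shells = 1, grid = g)
  tp1 <- total_projection(sh1)
  expect_equal(tp1$values, sh1$values[, , 1])
})

test_that("thickness normalization cancels a varying wall", {
  # wall built between two confocal shells of the model, so its thickness
  # varies with mu; a unit field must map to a constant after
  # normalization
  m <- make_test_model()
  f <- m$focal_distance
  lam_epi <- optheart:::.lam_of_model(m)
  lam_endo <- lam_epi - 0.35
  n <- 80; vox <- 0.15
  ax <- (seq_len(n) - (n + 1) / 2) * vox
  gpts <- as.matrix(expand.grid(ax, ax, ax))
  lam <- matrix(cartesian_to_prolate(gpts, m)[, "lam"], nrow = n^3)
  epi_mask <- array(lam <= lam_epi, c(n, n, n))
  endo_mask <- array(lam <= lam_endo, c(n, n, n))
  g <- map_grid(20, 36)
  th <- wall_thickness(epi_mask, endo_mask, m, g, voxel_size = vox)
  unit <- opt_volume(array(1, c(n, n, n)), vox)
  sh <- sample_shells(unit, m, n_shells = 8, grid = g,
                      lambda_range = c(lam_endo, lam_epi))
  tp <- total_projection(sh, thickness_map = th, normalize = TRUE)
  keep <- tp$valid & (g$mu > 0.25 & g$mu < truncation_mu(m))
  vals <- tp$values[keep]
  # thickness itself varies substantially over the wall ...
  expect_gt(max(th$values[keep]) / min(th$values[keep]), 1.3)
  # ... yet the normalized unit field is flat
  expect_lt(stats::sd(vals) / mean(vals), 0.1)
  expect_equal(mean(vals), 1, tolerance = 0.15)

  # zero thickness invalidates a node rather than dividing
  th0 <- th
  th0$values[5, 1] <- 0
  tp0 <- total_projection(sh, thickness_map = th0, normalize = TRUE)
  expect_false(tp0$valid[5, 1])
})

test_that("Bull's-Eye re-gridding preserves structure and totals", {
  m <- make_test_model()
  g <- map_grid(30, 60)
  const <- surface_map(matrix(4, 30, 60), grid = g,
                       truncation_mu = truncation_mu(m))
  be <- bulls_eye(const, n_pixels = 101)
  expect_equal(max(abs(be$values[be$valid] - 4)), 0)

  # one hot theta column becomes a radial sector
  hot <- matrix(0, 30, 60); hot[, 15] <- 1
  mh <- surface_map(hot, grid = g, truncation_mu = truncation_mu(m))
  beh <- bulls_eye(mh, n_pixels = 101)
  th_hot <- g$theta[15]
  np <- 101; xy <- seq(-1, 1, length.out = np)
  ang <- atan2(matrix(xy, np, np, byrow = TRUE), matrix(xy, np, np)) %% (2 * pi)
  sector <- abs(ang - th_hot) < 0.2 & beh$valid
  anti <- abs(ang - ((th_hot + pi) %% (2 * pi))) < 0.2 & beh$valid
  expect_gt(mean(beh$values[sector]), 50 * max(mean(beh$values[anti]), 1e-9))

  # area-weighted total is conserved under re-gridding
  set.seed(51)
  smooth <- outer(sin(g$mu * 2) + 1.5, cos(g$theta) + 1.5)
  ms <- surface_map(smooth, grid = g, truncation_mu = truncation_mu(m))
  bes <- bulls_eye(ms, n_pixels = 201)
  mu_rim <- truncation_mu(m)
  w_mu <- ifelse(g$mu <= mu_rim, g$mu, 0)  # area element: mu dmu dtheta
  cyl_total <- sum(outer(w_mu, rep(1, g$n_theta)) * smooth) *
    (g$mu_max / g$n_mu) * (2 * pi / g$n_theta)
  px <- (2 / 200)^2
  disk_total <- sum(bes$values[bes$valid]) * px * mu_rim^2
  expect_equal(disk_total, cyl_total, tolerance = 0.02 * abs(cyl_total))
})

test_that("AHA partition yields the standard 17 segments", {
  m <- make_test_model()
  g <- map_grid(48, 96)
  tmu <- truncation_mu(m)
  labs <- aha17_labels(g, truncation_mu = tmu)
  expect_equal(sort(unique(labs[!is.na(labs)])), 1:17)
  # apex center carries the apical-cap label
  expect_equal(unname(labs[1, ]), rep(17L, 96))
  # nodes beyond the truncation line are unlabeled
  expect_true(all(is.na(labs[g$mu > tmu, ])))
  # rings partition the retained range at exact thirds
  b <- attr(labs, "boundaries")
  expect_equal(unname(b[c("apical", "mid", "basal")]),
               c(tmu / 3, 2 * tmu / 3, tmu))
  in_basal <- g$mu >= 2 * tmu / 3 & g$mu <= tmu
  expect_true(all(labs[in_basal, ] %in% 1:6))

  # a uniform map has equal segment means
  um <- surface_map(matrix(3, 48, 96), grid = g, truncation_mu = tmu)
  st <- aha17_segment_stats(um, labs)
  expect_equal(st$mean, rep(3, 17))

  # rotating the theta origin by 60 degrees permutes 6-sector rings
  labs2 <- aha17_labels(g, truncation_mu = tmu, theta_offset = pi / 3)
  basal_row <- which(in_basal)[1]
  shift <- g$n_theta / 6
  expect_equal(labs2[basal_row, ],
               labs[basal_row, c((g$n_theta - shift + 1):g$n_theta,
                                 1:(g$n_theta - shift))])
})

test_that("ratio classification respects thresholds and invariances", {
  g <- map_grid(8, 16)
  base <- matrix(1, 8, 16)
  mk <- function(v) surface_map(v, grid = g, truncation_mu = pi)
  a <- base; a[1, 1] <- 1.2; a[2, 1] <- 1.0; a[3, 1] <- 0.85
  b <- base; b[4, 1] <- 0
  cls <- ratio_classify(mk(a), mk(b))
  expect_equal(cls[1, 1], "high")
  expect_equal(cls[2, 1], "intermediate")
  expect_equal(cls[3, 1], "low")
  expect_equal(cls[4, 1], "undefined")
  # boundary values are intermediate (closed interval)
  a2 <- base; a2[5, 1] <- 1.1; a2[6, 1] <- 0.9
  cls2 <- ratio_classify(mk(a2), mk(base))
  expect_equal(cls2[5, 1], "intermediate")
  expect_equal(cls2[6, 1], "intermediate")
  # scale invariance
  cls3 <- ratio_classify(mk(7.3 * a), mk(7.3 * b))
  expect_identical(cls3 == cls, cls == cls)
  expect_identical(as.vector(cls3), as.vector(cls))
  expect_error(ratio_classify(mk(a), surface_map(matrix(1, 4, 4))), "grid")
})

test_that("bead hypoperfusion delineates the infarct", {
  ph <- small_phantom(n = 48)
  set.seed(52)
  noisy_beads <- ph$beads$values +
    array(rnorm(48^3, 0, 0.1), c(48, 48, 48))
  inf <- infarct_mask_from_beads(opt_volume(pmax(noisy_beads, 0), 0.22),
                                 ph$myocardium_mask)
  dice <- 2 * sum(inf & ph$infarct_mask) /
    (sum(inf) + sum(ph$infarct_mask))
  expect_gte(dice, 0.85)

  uni <- infarct_mask_from_beads(
    opt_volume(array(1, dim(ph$beads$values)) * ph$myocardium_mask, 0.22),
    ph$myocardium_mask)
  expect_true(attr(uni, "empty"))
  expect_equal(sum(uni), 0)
  expect_error(infarct_mask_from_beads(
    opt_volume(array(0, dim(ph$beads$values)), 0.22), ph$myocardium_mask),
    "all zero")

  # fraction-of-median method agrees on the easy phantom
  inf2 <- infarct_mask_from_beads(opt_volume(pmax(noisy_beads, 0), 0.22),
                                  ph$myocardium_mask, method = "fraction")
  dice2 <- 2 * sum(inf2 & ph$infarct_mask) /
    (sum(inf2) + sum(ph$infarct_mask))
  expect_gte(dice2, 0.85)
})

test_that("distance-band densities recover construction parameters", {
  ph <- small_phantom(n = 48, probe_contrast = 1)
  bd <- distance_band_density(ph$probe_a, ph$infarct_mask,
                              ph$myocardium_mask, voxel_size = 0.22)
  expect_false(any(bd$empty))
  expect_equal(bd$density[1] / bd$density[2], 1, tolerance = 1e-12)

  ph3 <- small_phantom(n = 64, voxel = 0.2,
                       epi_semi_axes = c(3.2, 3.2, 5.2),
                       endo_semi_axes = c(2.3, 2.3, 4.3),
                       probe_profile = "bands", probe_contrast = 3)
  bd3 <- distance_band_density(ph3$probe_a, ph3$infarct_mask,
                               ph3$myocardium_mask, voxel_size = 0.2)
  expect_equal(bd3$density[1] / bd3$density[2], 3, tolerance = 1e-12)
  expect_true(attr(bd3, "remote_fraction") >= 0 &&
                attr(bd3, "remote_fraction") <= 1)

  # degenerate geometry: infarct covering the whole myocardium
  expect_warning(
    bd0 <- distance_band_density(ph$probe_a, ph$myocardium_mask,
                                 ph$myocardium_mask, voxel_size = 0.22),
    "no myocardium")
  expect_true(all(bd0$empty))
})

test_that("shell integration conserves the volume integral", {
  # moderately fine grid: the shell-quadrature total over the confocal
  # wall matches the direct voxel integral of the field over that region
  m <- lv_ellipsoid(c(0, 0, 0), diag(3), c(3, 3, 4.6))
  f <- m$focal_distance
  lam_epi <- optheart:::.lam_of_model(m)
  lam_endo <- lam_epi - 0.3
  n <- 128; vox <- 0.1
  ax <- (seq_len(n) - (n + 1) / 2) * vox
  xm <- array(rep(ax, times = n * n), c(n, n, n))
  zm <- array(rep(ax, each = n * n), c(n, n, n))
  field <- 1 + 0.3 * zm + 0.2 * xm
  gpts <- as.matrix(expand.grid(ax, ax, ax))
  pc <- cartesian_to_prolate(gpts, m)
  region <- array(pc[, "lam"] >= lam_endo & pc[, "lam"] <= lam_epi,
                  c(n, n, n))
  direct <- sum(field[region]) * vox^3

  n_sh <- 24L
  g <- map_grid(60, 120)
  sh <- sample_shells(opt_volume(field, vox), m, n_shells = n_sh, grid = g,
                      lambda_range = c(lam_endo, lam_epi))
  lam_mid <- sh$lambdas
  dlam <- diff(lam_mid[1:2])
  mu_m <- matrix(g$mu, g$n_mu, g$n_theta)
  quad <- 0
  for (s in seq_len(n_sh)) {
    h_mu <- f * sqrt(sinh(lam_mid[s])^2 + sin(mu_m)^2)
    h_th <- f * sinh(lam_mid[s]) * sin(mu_m)
    dv <- h_mu * h_mu * h_th * (g$mu_max / g$n_mu) *
      (2 * pi / g$n_theta) * dlam
    quad <- quad + sum(sh$values[, , s] * dv)
  }
  expect_equal(quad, direct, tolerance = 0.05 * abs(direct))
})
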