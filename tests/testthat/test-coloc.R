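gauss_blob <- function(n, center, sigma, amp = 1) {
  ax <- seq_len(n)
  xm <- array(rep(ax, times = n * n), c(n, n, n))
  ym <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  zm <- array(rep(ax, each = n * n), c(n, n, n))
  amp * exp(-((xm - center[1])^2 + (ym - center[2])^2 +
                (zm - center[3])^2) / (2 * sigma^2))
}

test_that("overlap coefficient has the stated limits and invariances", {
  set.seed(61)
  v <- array(runif(24^3), c(24, 24, 24))
  expect_equal(overlap_coefficient(v, v), 1, tolerance = 1e-12)
  expect_equal(overlap_coefficient(v, 3 * v), 1, tolerance = 1e-12)

  a <- array(0, c(24, 24, 24)); a[1:10, , ] <- 1
  b <- array(0, c(24, 24, 24)); b[15:24, , ] <- 1
  expect_equal(overlap_coefficient(a, b), 0)

  expect_error(overlap_coefficient(a, array(0, c(24, 24, 24))), "all zero")
  expect_error(overlap_coefficient(a, b[1:10, 1:10, 1:10]), "share shape")

  # Cauchy-Schwarz: r <= 1, equality only under proportionality
  for (k in 1:5) {
    x <- array(runif(10^3), c(10, 10, 10))
    y <- array(runif(10^3), c(10, 10, 10))
    r <- overlap_coefficient(x, y)
    expect_true(r >= 0 && r <= 1)
    expect_lt(r, 1 - 1e-6)
  }
})

test_that("translational CCF peaks at the constructed shift", {
  b <- gauss_blob(32, c(16, 16, 16), 3)
  cc_self <- ccf_translational(b, b, max_shift = 3)
  expect_equal(cc_self$argmax_shift, c(0, 0, 0))
  expect_equal(cc_self$max_r, 1, tolerance = 1e-12)
  expect_equal(cc_self$r_grid["0", "0", "0"], 1, tolerance = 1e-12)

  shifted <- optheart:::.shift3(b, c(3, 0, 0))
  cc <- ccf_translational(b, shifted, max_shift = 4)
  expect_equal(cc$argmax_shift, c(-3, 0, 0))
  expect_equal(cc$max_r, 1, tolerance = 1e-9)

  set.seed(62)
  n1 <- array(runif(20^3), c(20, 20, 20))
  n2 <- array(runif(20^3), c(20, 20, 20))
  n1[n1 < 0.9] <- 0; n2[n2 < 0.9] <- 0
  cc_noise <- ccf_translational(n1, n2, max_shift = 3)
  expect_lt(cc_noise$max_r, 0.2)

  expect_error(ccf_translational(b, b, max_shift = 40), "smaller")
})

test_that("CCF obeys swap symmetry and translation equivariance", {
  set.seed(63)
  a <- gauss_blob(24, c(12, 13, 11), 3)
  b <- gauss_blob(24, c(13, 11, 12), 4)
  # zero the borders so integer shifts move no mass across the edge
  zero_margin <- function(v, w = 4) {
    n <- dim(v)[1]
    v[c(1:w, (n - w + 1):n), , ] <- 0
    v[, c(1:w, (n - w + 1):n), ] <- 0
    v[, , c(1:w, (n - w + 1):n)] <- 0
    v
  }
  a <- zero_margin(a); b <- zero_margin(b)
  cab <- ccf_translational(a, b, max_shift = 2)
  cba <- ccf_translational(b, a, max_shift = 2)
  expect_equal(cab$r_grid, cba$r_grid[5:1, 5:1, 5:1],
               ignore_attr = TRUE, tolerance = 1e-12)

  # shifting both volumes identically leaves the CCF unchanged (padded
  # volumes: nothing crosses the border)
  a2 <- optheart:::.shift3(a, c(2, -1, 1))
  b2 <- optheart:::.shift3(b, c(2, -1, 1))
  c2 <- ccf_translational(a2, b2, max_shift = 2)
  expect_equal(c2$r_grid, cab$r_grid, tolerance = 1e-12)
})

test_that("rotational CCF profiles localize a constructed rotation", {
  m <- lv_ellipsoid(c(0, 0, 0), diag(3), c(2, 2, 3.2))
  n <- 40; vox <- 0.2
  # two equal off-axis blobs on opposite sides: a rotation moves them in
  # opposite tangential directions, so no translation can absorb it and
  # the translational argmax stays at zero
  v1 <- gauss_blob(n, c(28, 20.5, 20), 2.5) +
    gauss_blob(n, c(13, 20.5, 20), 2.5)
  cc <- ccf_translational(v1, v1, max_shift = 2)
  rot <- ccf_rotational(opt_volume(v1, vox), opt_volume(v1, vox), m, cc,
                        angles_deg = seq(-12, 12, 4))
  expect_equal(unname(rot$r[rot$angles_deg == 0, "long"]), cc$max_r,
               tolerance = 1e-12)

  R10 <- optheart:::.rotation_matrix(c(0, 0, 1), 10)
  ctr <- rep((n + 1) / 2, 3)
  v2 <- optheart:::.rotate_volume(v1, R10, ctr)
  cc2 <- ccf_translational(v1, v2, max_shift = 2)
  rot2 <- ccf_rotational(opt_volume(v1, vox), opt_volume(v2, vox), m, cc2,
                         angles_deg = seq(-20, 20, 2))
  prof <- rot2$r[, "long"]
  expect_equal(rot2$angles_deg[which.max(prof)], -10)
  expect_gte(max(prof), 0.98)

  # axisymmetric volume: long-axis rotations leave r at 1
  ax_sym <- gauss_blob(n, c(20.5, 20.5, 26), 4)
  cc3 <- ccf_translational(ax_sym, ax_sym, max_shift = 1)
  rot3 <- ccf_rotational(opt_volume(ax_sym, vox), opt_volume(ax_sym, vox),
                         m, cc3, angles_deg = seq(-8, 8, 4))
  expect_true(all(rot3$r[, "long"] > 0.999))
  expect_error(ccf_rotational(opt_volume(v1, vox), opt_volume(v1, vox), m,
                              cc, angles_deg = numeric(0)), "empty")
})

test_that("CCF FWHM matches the Gaussian closed form", {
  # blob sigma sqrt(2): the CCF of the blob against itself is Gaussian
  # with sigma 2, FWHM 2*2*sqrt(2 ln 2) ~ 4.71 voxels
  b <- gauss_blob(40, c(20, 20, 20), sqrt(2))
  cc <- ccf_translational(b, b, max_shift = 6)
  for (ax in 1:3) {
    w <- ccf_fwhm(cc, ax)
    expect_false(attr(w, "lower_bound"))
    expect_equal(as.numeric(w), 2 * 2 * sqrt(2 * log(2)), tolerance = 0.1)
  }

  # colocated single-voxel volumes: support-limited width
  d1 <- array(0, c(16, 16, 16)); d1[8, 8, 8] <- 1
  cc_d <- ccf_translational(d1, d1, max_shift = 2)
  w_d <- ccf_fwhm(cc_d, 1)
  expect_true(as.numeric(w_d) >= 0.5 && as.numeric(w_d) <= 2)

  # wider probe halos give strictly wider CCF peaks
  widths <- c(1.2, 2, 3.2)
  fw <- vapply(widths, function(s) {
    v <- gauss_blob(40, c(20, 20, 20), s)
    as.numeric(ccf_fwhm(ccf_translational(v, v, max_shift = 12), 1))
  }, numeric(1))
  expect_true(all(diff(fw) > 0))

  # a profile that never falls below half max is flagged as lower bound
  wide <- gauss_blob(32, c(16, 16, 16), 10)
  cc_w <- ccf_translational(wide, wide, max_shift = 2)
  w_w <- ccf_fwhm(cc_w, 1)
  expect_true(attr(w_w, "lower_bound"))
})

test_that("model-masked overlap restricts analysis to the retained LV", {
  ph <- small_phantom(n = 40, voxel = 0.25)
  m <- ph$true_ellipsoid
  r <- overlap_coefficient(ph$probe_a, ph$probe_b, mask = m)
  expect_true(r > 0 && r <= 1)
  msk <- optheart:::.retained_region_mask(m, dim(ph$lv_mask), 0.25)
  # mask agrees with the phantom's own truncated LV interior
  expect_gt(sum(msk & ph$lv_mask) / sum(ph$lv_mask), 0.95)
})
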