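test_that("absorbance conversion follows Beer-Lambert closed forms", {
  ang <- seq(0, 170, 10)
  flat <- opt_sinogram(matrix(1, 32, 18), ang)
  expect_equal(transmission_to_absorbance(flat, 1)$values,
               matrix(0, 32, 18))

  one_ray <- matrix(1, 32, 18)
  one_ray[10, ] <- exp(-1)
  A <- transmission_to_absorbance(opt_sinogram(one_ray, ang), 1)
  expect_equal(A$values[10, ], rep(1, 18), tolerance = 1e-12)

  # nonpositive rays are clipped to the floor and counted
  bad <- one_ray; bad[3, 1] <- 0
  A2 <- transmission_to_absorbance(opt_sinogram(bad, ang), 1)
  expect_equal(attr(A2, "n_clipped"), 1L)
  expect_equal(A2$values[3, 1], -log(1e-6))
  expect_error(transmission_to_absorbance(flat, 0), "positive")
})

test_that("disk absorbance and FBP are quantitatively correct", {
  vox <- 0.1; mu <- 0.1; R <- 20
  ds <- disk_sinogram(n = 64, mu = mu, radius = R, vox = vox)
  A <- transmission_to_absorbance(ds$sino, 1)
  expect_equal(A$values[33, 1], mu * 2 * R * vox, tolerance = 0.03)

  rec <- fbp_slice(A, "shepp-logan", voxel_size = vox)
  expect_equal(dim(rec), c(64, 64))
  expect_equal(mean(rec[ds$disk$rr <= R - 2]), mu, tolerance = 0.05)
  expect_lt(max(abs(rec[ds$disk$rr > R + 6])), 0.1 * mu)

  # all filters reconstruct the plateau
  for (f in c("ram-lak", "hann")) {
    rf <- fbp_slice(A, f, voxel_size = vox)
    expect_equal(mean(rf[ds$disk$rr <= R - 2]), mu, tolerance = 0.06)
  }
})

test_that("FBP is linear and maps zero to zero", {
  ang <- seq(0, 179, 1)
  z <- fbp_slice(matrix(0, 32, 180), voxel_size = 0.1, angles = ang)
  expect_equal(max(abs(z)), 0)
  set.seed(31)
  s1 <- matrix(runif(32 * 180), 32)
  s2 <- matrix(runif(32 * 180), 32)
  r12 <- fbp_slice(2 * s1 - 3 * s2, voxel_size = 0.1, angles = ang)
  r1 <- fbp_slice(s1, voxel_size = 0.1, angles = ang)
  r2 <- fbp_slice(s2, voxel_size = 0.1, angles = ang)
  expect_equal(r12, 2 * r1 - 3 * r2, tolerance = 1e-10)
})

test_that("two point sources reconstruct at their true positions", {
  n <- 64
  tp <- array(0, c(n, n, 1)); tp[20, 32, 1] <- 1; tp[44, 40, 1] <- 1
  pr <- forward_project(tp, seq(0, 179, 1), "fluorescence",
                        absorption = array(0, c(n, n, 1)), voxel_size = 0.1)
  rec <- fbp_slice(projection_sinogram(pr, 1), voxel_size = 0.1)
  p1 <- which(rec == max(rec), arr.ind = TRUE)[1, ]
  rec2 <- rec
  rec2[(p1[1] - 3):(p1[1] + 3), (p1[2] - 3):(p1[2] + 3)] <- 0
  p2 <- which(rec2 == max(rec2), arr.ind = TRUE)[1, ]
  peaks <- rbind(p1, p2)[order(rbind(p1, p2)[, 1]), ]
  expect_true(all(abs(peaks - rbind(c(20, 32), c(44, 40))) <= 1))
})

test_that("FBP matches an independent brute-force implementation", {
  set.seed(32)
  n <- 32
  ang <- seq(0, 176.25, length.out = 48)
  sino <- matrix(runif(n * 48), n, 48)
  for (f in c("ram-lak", "shepp-logan", "hann")) {
    a <- fbp_slice(sino, f, voxel_size = 0.2, angles = ang)
    b <- fbp_bruteforce(sino, ang, f, voxel_size = 0.2)
    expect_lt(rms(a - b) / rms(b), 1e-9)
  }
})

test_that("FBP validates angle geometry", {
  expect_error(fbp_slice(matrix(1, 16, 4), angles = c(0, 45, 90, 135)),
               "at least 8")
  expect_error(fbp_slice(matrix(1, 16, 9),
                         angles = c(0, 10, 30, 40, 60, 80, 100, 140, 179)),
               "non-uniform")
  expect_error(fbp_slice(matrix(1, 16, 10), angles = seq(0, 90, 10)),
               "span")
})

test_that("Born normalization has the stated limits", {
  f <- matrix(runif(32 * 10), 32)
  t1 <- matrix(2, 32, 10)
  b <- born_normalize(f, t1, epsilon = 1e-6)
  expect_equal(b, f / (2 + 1e-6), tolerance = 1e-12)
  expect_equal(born_normalize(matrix(0, 32, 10), t1), matrix(0, 32, 10))
  expect_error(born_normalize(f, matrix(1, 16, 10)), "shape")
  expect_error(born_normalize(f, t1, epsilon = 0), "positive")
  expect_error(born_normalize(f, t1, epsilon = -1), "positive")
})

test_that("Born normalization recovers absorber-shadowed inclusions", {
  # two identical inclusions, one inside a strong absorber: without the
  # Born ratio the deep one reconstructs dimmer; the error grows with
  # absorber strength while the normalized pipeline stays calibrated
  n <- 64; vox <- 0.15
  xy <- (1:n) - (n + 1) / 2
  xm <- matrix(xy, n, n); ym <- matrix(xy, n, n, byrow = TRUE)
  rr2 <- xm^2 + ym^2
  deep <- exp(-rr2 / (2 * 2^2))
  shal <- exp(-((xm - 22)^2 + ym^2) / (2 * 2^2))
  probe <- array(deep + shal, c(n, n, 1))
  ang <- seq(0, 358, 2)
  m_deep <- rr2 <= 1.5^2
  m_shal <- (xm - 22)^2 + ym^2 <= 1.5^2
  ratio_for <- function(mu0, born) {
    mu <- array(0.01 + mu0 * (rr2 <= 8^2), c(n, n, 1))
    pt <- forward_project(mu, ang, "transmission", voxel_size = vox)
    pf <- forward_project(probe, ang, "fluorescence", absorption = mu,
                          voxel_size = vox)
    v <- reconstruct_volume(pf, "fluorescence", transmission = pt,
                            voxel_size = vox,
                            config = recon_config(born = born), slices = 1)
    mean(v$values[, , 1][m_deep]) / mean(v$values[, , 1][m_shal])
  }
  strengths <- c(0.3, 0.6, 0.9)
  un <- vapply(strengths, ratio_for, numeric(1), born = FALSE)
  no <- vapply(strengths, ratio_for, numeric(1), born = TRUE)
  expect_true(all(diff(un) < 0))            # deeper shadowing, worse ratio
  expect_true(all(abs(no - 1) < 0.1))       # normalized stays calibrated
  expect_lt(un[2], 0.7)
})

test_that("reconstruct_volume recovers the phantom absorption map", {
  ph <- small_phantom(n = 48)
  ang <- seq(0, 179, length.out = 90)
  pr <- forward_project(ph$absorption, ang, "transmission")
  vol <- reconstruct_volume(pr, "absorption", voxel_size = 0.22)
  expect_equal(dim(vol$values)[3], dim(pr$frames)[2])
  expect_gt(stats::cor(as.vector(vol$values),
                       as.vector(ph$absorption$values)), 0.9)
})

test_that("a probe-free fluorescence channel reconstructs to zero", {
  ph <- small_phantom(n = 32)
  ang <- seq(0, 350, 10)
  pt <- forward_project(ph$absorption, ang, "transmission")
  pf <- forward_project(opt_volume(array(0, c(32, 32, 32)), 0.22), ang,
                        "fluorescence", absorption = ph$absorption)
  vol <- reconstruct_volume(pf, "fluorescence", transmission = pt,
                            voxel_size = 0.22, slices = c(10, 16, 22))
  expect_lt(max(abs(vol$values)), 1e-8)
  expect_error(reconstruct_volume(pf, "fluorescence", voxel_size = 0.22),
               "transmission")
})
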