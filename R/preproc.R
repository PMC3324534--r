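# Sinogram-domain corrections. The pipeline order is fixed: source-power
# equalization, then ring (detector-gain) correction, then denoising, all
# on intensity projections before any log/ratio transform and before
# backprojection.

#' Equalize per-angle source power on a sinogram
#'
#' Lamp/laser power fluctuations multiply whole projections and appear as
#' vertical stripes in the sinogram. Each angle's column is rescaled so
#' that its mean over a reference region of detector bins known to lie
#' outside the sample shadow matches the global reference mean.
#'
#' @param sinogram an [opt_sinogram] (intensity domain).
#' @param margin fraction of detector bins on each edge used as the
#'   reference region (default outermost 10% per side), ignored when
#'   `ref_bins` is given.
#' @param ref_bins explicit integer vector of reference detector bins.
#' @return The corrected [opt_sinogram] with attributes `factors` (the
#'   per-angle scale factors applied) and `overlap_warning` (TRUE when the
#'   reference region shows high residual variance, suggesting it overlaps
#'   the sample support).
#' @export
power_equalize <- function(sinogram, margin = 0.1, ref_bins = NULL) {
  .assert(inherits(sinogram, "opt_sinogram"), "`sinogram` must be opt_sinogram")
  v <- sinogram$values
  n <- nrow(v)
  if (is.null(ref_bins)) {
    k <- max(1L, ceiling(margin * n))
    ref_bins <- c(seq_len(k), seq(n - k + 1L, n))
  }
  .assert(length(ref_bins) > 0 && all(ref_bins >= 1 & ref_bins <= n),
          "empty or out-of-range reference region")
  col_ref <- colMeans(v[ref_bins, , drop = FALSE])
  .assert(all(col_ref > 0), "reference region has nonpositive mean intensity")
  factors <- mean(col_ref) / col_ref
  out <- sweep(v, 2, factors, "*")
  # after removing the per-angle factor, residual variation of a reference
  # bin across angles indicates the sample shadow sweeping through it
  ref_corr <- out[ref_bins, , drop = FALSE]
  cv <- apply(ref_corr, 1, stats::sd) / pmax(rowMeans(ref_corr), 1e-12)
  overlap <- stats::median(cv) > 0.1
  if (overlap)
    warning("power_equalize: reference region appears to overlap the sample support")
  res <- opt_sinogram(out, sinogram$angles, sinogram$channel, sinogram$slice)
  attr(res, "factors") <- factors
  attr(res, "overlap_warning") <- overlap
  res
}

#' Remove fixed detector-column gain (ring artifacts)
#'
#' Fixed per-detector-bin gain errors become rows of the sinogram that are
#' consistently too bright or too dark, and reconstruct as rings. The gain
#' of each bin is estimated as the ratio of its mean over angles to a
#' smoothed (moving-average) version of that mean profile; each sinogram
#' row is divided by its gain.
#'
#' @param sinogram an [opt_sinogram] with at least 16 angles.
#' @param window_frac smoothing window for the mean-profile baseline, as a
#'   fraction of the detector bin count (default 5%).
#' @return Corrected [opt_sinogram] with attributes `gains` (per-bin gain
#'   estimates) and `skipped` (bins with near-zero mean left untouched).
#' @export
ring_correct <- function(sinogram, window_frac = 0.05) {
  .assert(inherits(sinogram, "opt_sinogram"), "`sinogram` must be opt_sinogram")
  v <- sinogram$values
  .assert(ncol(v) >= 16L, "ring_correct needs at least 16 angles")
  n <- nrow(v)
  m <- rowMeans(v)
  # stage 1: running-median baseline. Exact on monotone stretches of the
  # clean mean profile (so sharp sample-edge kinks produce no spurious
  # gain), and robust to dense random per-bin gains.
  w <- max(5L, as.integer(round(window_frac * n)))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- stats::runmed(m, w, endrule = "median")
  skipped <- abs(sm) < 1e-12 * max(abs(m), 1e-300) | abs(m) < 1e-300
  gains <- ifelse(skipped, 1, m / sm)
  # stage 2: a median baseline underestimates an isolated spike by the
  # local profile slope; bins flagged as clear outliers get a
  # slope-correct baseline interpolated from the unflagged bins
  dev <- abs(gains - 1)
  thr <- max(5 * stats::mad(dev, center = 0), 5e-3)
  flag <- dev > thr & !skipped
  if (any(flag) && sum(!flag) >= 2L) {
    base <- stats::approx(x = which(!flag), y = m[!flag],
                          xout = which(flag), rule = 2)$y
    gains[flag] <- m[flag] / base
  }
  out <- v / gains
  res <- opt_sinogram(out, sinogram$angles, sinogram$channel, sinogram$slice)
  attr(res, "gains") <- gains
  attr(res, "skipped") <- skipped
  res
}

#' Denoise a sinogram
#'
#' Applied to projections before backprojection. `"median2d"` is a 2D
#' median filter (constant-time implementation from EBImage; the monotone
#' rescale to its required unit range commutes exactly with the median).
#' `"bm3d"` is a reduced block-matching collaborative filter: similar
#' patches are grouped, jointly DCT-transformed across the group, hard
#' thresholded, inverted and aggregated with sparsity weights.
#'
#' @param sinogram an [opt_sinogram].
#' @param method `"median2d"` or `"bm3d"`.
#' @param params method parameters. median2d: `radius` (default 1). bm3d:
#'   `sigma` (noise SD, estimated from the high-frequency residual when
#'   NULL), `patch` (8), `step` (4), `search` (16), `K` (8), `hard`
#'   (threshold multiple, 2.7).
#' @return Denoised [opt_sinogram].
#' @export
denoise <- function(sinogram, method = c("median2d", "bm3d"),
                    params = list()) {
  .assert(inherits(sinogram, "opt_sinogram"), "`sinogram` must be opt_sinogram")
  method <- match.arg(method)
  v <- sinogram$values
  out <- switch(method,
    median2d = .median2d(v, params$radius %||% 1L),
    bm3d = .bm3d_sino(v, sigma = params$sigma,
                      patch = params$patch %||% 8L,
                      step = params$step %||% 4L,
                      search = params$search %||% 16L,
                      K = params$K %||% 8L,
                      hard = params$hard %||% 2.7))
  opt_sinogram(out, sinogram$angles, sinogram$channel, sinogram$slice)
}

# 2D median via EBImage's constant-time filter; rescaling to [0,1] is
# monotone so the median is unaffected
.median2d <- function(m, radius) {
  rng <- range(m)
  if (diff(rng) == 0) return(m)
  x01 <- (m - rng[1]) / diff(rng)
  y <- EBImage::medianFilter(x01, size = as.integer(radius))
  y * diff(rng) + rng[1]
}

# orthonormal DCT-II basis
.dct_basis <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- sqrt(1 / n)
  D
}

# reduced BM3D-style collaborative hard-threshold filter
.bm3d_sino <- function(m, sigma = NULL, patch = 8L, step = 4L,
                       search = 16L, K = 8L, hard = 2.7) {
  d <- dim(m)
  patch <- min(patch, d[1], d[2])
  if (is.null(sigma)) {
    resid <- m - .median2d(m, 1L)
    sigma <- stats::mad(resid)
  }
  D <- .dct_basis(patch)
  acc <- array(0, d); wacc <- array(0, d)
  ri <- unique(c(seq(1L, d[1] - patch + 1L, by = step), d[1] - patch + 1L))
  rj <- unique(c(seq(1L, d[2] - patch + 1L, by = step), d[2] - patch + 1L))
  thr <- hard * sigma
  for (i in ri) for (j in rj) {
    ref <- m[i:(i + patch - 1L), j:(j + patch - 1L)]
    ci <- unique(pmin(pmax(seq(i - search, i + search, by = 2L), 1L),
                      d[1] - patch + 1L))
    cj <- unique(pmin(pmax(seq(j - search, j + search, by = 2L), 1L),
                      d[2] - patch + 1L))
    cand <- as.matrix(expand.grid(ci = ci, cj = cj))
    dist <- vapply(seq_len(nrow(cand)), function(r) {
      p <- m[cand[r, 1]:(cand[r, 1] + patch - 1L),
             cand[r, 2]:(cand[r, 2] + patch - 1L)]
      mean((p - ref)^2)
    }, numeric(1))
    pick <- cand[order(dist)[seq_len(min(K, nrow(cand)))], , drop = FALSE]
    k_eff <- nrow(pick)
    stack <- vapply(seq_len(k_eff), function(r) {
      D %*% m[pick[r, 1]:(pick[r, 1] + patch - 1L),
              pick[r, 2]:(pick[r, 2] + patch - 1L)] %*% t(D)
    }, matrix(0, patch, patch))
    Dk <- .dct_basis(k_eff)
    cf <- Dk %*% matrix(aperm(stack, c(3, 1, 2)), k_eff)
    kept <- abs(cf) >= thr
    cf[!kept] <- 0
    w <- 1 / max(1, sum(kept))
    back <- aperm(array(t(Dk) %*% cf, c(k_eff, patch, patch)), c(2, 3, 1))
    for (r in seq_len(k_eff)) {
      ii <- pick[r, 1]:(pick[r, 1] + patch - 1L)
      jj <- pick[r, 2]:(pick[r, 2] + patch - 1L)
      acc[ii, jj] <- acc[ii, jj] + w * t(D) %*% back[, , r] %*% D
      wacc[ii, jj] <- wacc[ii, jj] + w
    }
  }
  ifelse(wacc > 0, acc / pmax(wacc, 1e-300), m)
}
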