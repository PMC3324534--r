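# Tomographic inversion: absorption maps by filtered backprojection of
# -log transmission; fluorescence distributions by Born-ratio
# normalization of each projection against its excitation-wavelength
# transmission frame, then FBP of the normalized stack.

#' Transmission sinogram to absorbance (Radon domain)
#'
#' Beer-Lambert inversion per ray: `-ln(I / I0)`, the line integral of the
#' attenuation coefficient (dimensionless, mm x 1/mm).
#'
#' @param sinogram transmission-intensity [opt_sinogram] (values > 0).
#' @param reference sample-free illumination `I0`: scalar, per-detector-bin
#'   vector, or matrix matching the sinogram.
#' @param floor_frac nonpositive ratios are clipped to this fraction of 1
#'   before the log; the number of clipped rays is reported.
#' @return Absorbance [opt_sinogram] with attribute `n_clipped`.
#' @export
transmission_to_absorbance <- function(sinogram, reference,
                                       floor_frac = 1e-6) {
  .assert(inherits(sinogram, "opt_sinogram"), "`sinogram` must be opt_sinogram")
  .assert(all(reference > 0), "reference illumination must be positive")
  ratio <- sinogram$values / reference
  clipped <- !is.finite(ratio) | ratio <= 0
  ratio[clipped] <- floor_frac
  out <- opt_sinogram(-log(ratio), sinogram$angles, sinogram$channel,
                      sinogram$slice)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Born-ratio normalization of a fluorescence projection
#'
#' Divides a fluorescence frame (or sinogram) pixelwise by the
#' co-registered excitation-wavelength transmission frame. The sample's
#' heterogeneous absorption attenuates both the excitation light on its
#' way to a fluorophore and the emission on its way to the detector; in
#' the transillumination geometry their product cancels against the
#' transmitted excitation intensity, so the normalized stack is the input
#' that enters FBP for the fluorescence channels.
#'
#' @param fluor,transmission numeric matrices/arrays of identical shape,
#'   acquired at the same angle(s).
#' @param epsilon positive regularization added to the transmission
#'   denominator (default `1e-3` of its maximum).
#' @return The normalized projection, same shape.
#' @export
born_normalize <- function(fluor, transmission, epsilon = NULL) {
  .assert(all(dim(fluor) == dim(transmission)) &&
            length(fluor) == length(transmission),
          "fluorescence and transmission frames must share shape")
  if (is.null(epsilon)) epsilon <- 1e-3 * max(transmission)
  .assert(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0,
          "`epsilon` must be a single positive number")
  fluor / (transmission + epsilon)
}

.fbp_filters <- c("shepp-logan", "ram-lak", "hann")

# frequency response (cycles/sample grid of length M) of the named filter
.fbp_filter_response <- function(filter, M) {
  f <- .fftfreq(M)
  ramp <- 2 * abs(f)
  switch(filter,
    "ram-lak" = ramp,
    "shepp-logan" = {
      s <- rep(1, M)
      nz <- f != 0
      s[nz] <- sin(pi * f[nz]) / (pi * f[nz])
      ramp * s
    },
    "hann" = ramp * 0.5 * (1 + cos(2 * pi * f)))
}

#' Filtered backprojection of one sinogram
#'
#' Analytic inverse Radon transform for parallel-beam geometry: each
#' angle's projection is ramp-filtered in the frequency domain
#' (zero-padded FFT) and backprojected with linear interpolation. Angles
#' may span 180 or 360 degrees (the redundant half-turn is averaged
#' automatically through the angular quadrature weight).
#'
#' @param sinogram absorbance/line-integral [opt_sinogram] (values in
#'   physical units x mm when `voxel_size` is the detector bin pitch in
#'   mm), or a plain matrix together with `angles`.
#' @param filter `"shepp-logan"` (default), `"ram-lak"` or `"hann"`.
#' @param voxel_size detector bin pitch in mm; the output is then in
#'   physical units per mm (e.g. 1/mm for absorbance inputs).
#' @param angles required when `sinogram` is a matrix.
#' @return Square numeric matrix (side = detector bins) sampling the
#'   reconstructed slice on the detector grid.
#' @export
fbp_slice <- function(sinogram, filter = .fbp_filters, voxel_size = 1,
                      angles = NULL) {
  if (inherits(sinogram, "opt_sinogram")) {
    v <- sinogram$values
    angles <- sinogram$angles
  } else {
    v <- as.matrix(sinogram)
    .assert(!is.null(angles), "`angles` required for matrix input")
  }
  filter <- match.arg(filter)
  n <- nrow(v); nA <- ncol(v)
  .assert(nA >= 8L, "filtered backprojection needs at least 8 angles")
  dth <- diff(angles)
  .assert(all(dth > 0), "angles must be strictly increasing")
  .assert(max(dth) - min(dth) < 1e-6 * stats::median(dth) + 1e-9,
          "non-uniform angle spacing: resample the projections first")
  span <- (angles[nA] - angles[1]) + stats::median(dth)
  .assert(span >= 180 - 1e-6, "angles must span at least 180 degrees")

  M <- max(64L, 2^ceiling(log2(2 * n)))
  filt <- .fbp_filter_response(filter, M)
  pad <- rbind(v, matrix(0, M - n, nA))
  q <- Re(stats::mvfft(stats::mvfft(pad) * filt, inverse = TRUE)) / M
  q <- q[seq_len(n), , drop = FALSE]

  c0 <- (n + 1) / 2
  xc <- seq_len(n) - c0
  th <- angles * pi / 180
  acc <- matrix(0, n, n)
  for (k in seq_len(nA)) {
    t <- matrix(xc * cos(th[k]), n, n) +
      matrix(xc * sin(th[k]), n, n, byrow = TRUE) + c0
    i0 <- floor(t)
    inside <- i0 >= 1 & i0 <= n - 1
    i0c <- pmin(pmax(i0, 1L), n - 1L)
    fr <- t - i0c
    qa <- q[, k]
    val <- ((1 - fr) * qa[i0c] + fr * qa[i0c + 1L]) * inside
    acc <- acc + val
  }
  dth_rad <- stats::median(dth) * pi / 180
  # a full-turn acquisition covers every projection direction twice
  redundancy <- if (span > 270) 2 else 1
  acc * dth_rad / 2 / redundancy / voxel_size
}

#' Reconstruction pipeline configuration
#'
#' @param filter FBP filter name.
#' @param equalize,equalize_margin apply per-angle source-power
#'   equalization using the outermost `equalize_margin` fraction of
#'   detector bins per side as reference.
#' @param ring,ring_window_frac apply detector-gain ring correction with
#'   the given smoothing window fraction.
#' @param denoise `"none"`, `"median2d"` or `"bm3d"`; `denoise_params` as
#'   in [denoise()].
#' @param born divide fluorescence by the excitation transmission before
#'   FBP (disable only for method comparisons).
#' @param epsilon_frac Born denominator regularization as a fraction of
#'   the estimated unobstructed intensity.
#' @param clip_nonneg clip negative reconstructed values to zero (off by
#'   default: raw volumes stay linear).
#' @return A `recon_config` list.
#' @export
recon_config <- function(filter = "shepp-logan", equalize = TRUE,
                         equalize_margin = 0.1, ring = TRUE,
                         ring_window_frac = 0.05,
                         denoise = "none", denoise_params = list(),
                         born = TRUE, epsilon_frac = 1e-3,
                         clip_nonneg = FALSE) {
  .assert(filter %in% .fbp_filters, "unknown FBP filter")
  structure(list(filter = filter, equalize = equalize,
                 equalize_margin = equalize_margin, ring = ring,
                 ring_window_frac = ring_window_frac, denoise = denoise,
                 denoise_params = denoise_params, born = born,
                 epsilon_frac = epsilon_frac, clip_nonneg = clip_nonneg),
            class = "recon_config")
}

# preproc chain with enforced order: equalize -> ring -> denoise.
# `factors` and `gains` override the per-angle equalization factors and
# per-column ring gains: fluorescence frames reuse both estimates from
# their paired transmission channel — the sample-free margin of the
# transmission frames actually sees the source power, and the fixed CCD
# column gain is a property of the shared detector, while estimating it
# on a fluorescence sinogram would flatten genuine probe features that
# stay on the same detector bins across angles
.preproc_chain <- function(sino, config, factors = NULL, gains = NULL) {
  eq_factors <- NULL; ring_gains <- NULL
  if (config$equalize) {
    if (is.null(factors)) {
      sino <- suppressWarnings(
        power_equalize(sino, margin = config$equalize_margin))
      eq_factors <- attr(sino, "factors")
    } else {
      sino <- opt_sinogram(sweep(sino$values, 2, factors, "*"),
                           sino$angles, sino$channel, sino$slice)
      eq_factors <- factors
    }
  }
  if (config$ring) {
    if (is.null(gains)) {
      sino <- ring_correct(sino, config$ring_window_frac)
      ring_gains <- attr(sino, "gains")
    } else {
      sino <- opt_sinogram(sino$values / gains, sino$angles, sino$channel,
                           sino$slice)
      ring_gains <- gains
    }
  }
  if (!identical(config$denoise, "none"))
    sino <- denoise(sino, config$denoise, config$denoise_params)
  attr(sino, "eq_factors") <- eq_factors
  attr(sino, "ring_gains") <- ring_gains
  sino
}

#' Reconstruct a volume from a projection stack
#'
#' Applies the sinogram correction chain (source-power equalization, ring
#' correction, denoising), then per detector row either Beer-Lambert
#' absorbance + FBP (absorption channel) or Born-ratio normalization
#' against the excitation transmission + FBP (fluorescence channels), and
#' stacks the slices into a volume.
#'
#' @param proj [opt_projections] of the channel to reconstruct.
#' @param mode `"absorption"` or `"fluorescence"`.
#' @param transmission paired excitation-wavelength transmission
#'   [opt_projections]; required in fluorescence mode.
#' @param voxel_size detector bin pitch = reconstructed voxel edge, mm.
#' @param config a [recon_config()].
#' @param slices detector rows to reconstruct (default all).
#' @return [opt_volume] (1/mm for absorption; fluorophore density in
#'   arbitrary units for fluorescence) with attribute `diagnostics`
#'   (per-slice clipped-ray counts).
#' @export
reconstruct_volume <- function(proj, mode = c("absorption", "fluorescence"),
                               transmission = NULL, voxel_size = 1,
                               config = recon_config(), slices = NULL) {
  mode <- match.arg(mode)
  .assert(inherits(proj, "opt_projections"), "`proj` must be opt_projections")
  d <- dim(proj$frames)
  if (is.null(slices)) slices <- seq_len(d[2])
  n <- d[1]
  kref <- max(1L, ceiling(config$equalize_margin * n))
  ref_bins <- c(seq_len(kref), seq(n - kref + 1L, n))
  if (mode == "fluorescence")
    .assert(inherits(transmission, "opt_projections"),
            paste("fluorescence reconstruction requires the paired",
                  "excitation-wavelength transmission channel"))
  out <- array(0, c(n, n, length(slices)))
  n_clipped <- integer(length(slices))
  for (si in seq_along(slices)) {
    z <- slices[si]
    if (mode == "absorption") {
      s <- .preproc_chain(projection_sinogram(proj, z), config)
      I0 <- mean(s$values[ref_bins, ])
      A <- transmission_to_absorbance(s, I0)
      n_clipped[si] <- attr(A, "n_clipped")
      sl <- fbp_slice(A, filter = config$filter, voxel_size = voxel_size)
    } else {
      st <- .preproc_chain(projection_sinogram(transmission, z), config)
      sf <- .preproc_chain(projection_sinogram(proj, z), config,
                           factors = attr(st, "eq_factors"),
                           gains = attr(st, "ring_gains"))
      I0 <- mean(st$values[ref_bins, ])
      if (config$born) {
        b <- born_normalize(sf$values, st$values,
                            epsilon = config$epsilon_frac * I0)
        line_int <- b * I0
      } else {
        line_int <- sf$values / I0
      }
      sl <- fbp_slice(line_int, filter = config$filter,
                      voxel_size = voxel_size, angles = proj$angles)
    }
    if (config$clip_nonneg) sl <- pmax(sl, 0)
    out[, , si] <- sl
  }
  vol <- opt_volume(out, voxel_size,
                    channel = paste0(mode, "_recon"))
  attr(vol, "diagnostics") <- list(slices = slices, n_clipped = n_clipped)
  vol
}
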