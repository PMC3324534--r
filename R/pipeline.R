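# Configuration, file formats and end-to-end orchestration:
# phantom/ingest -> sinogram corrections -> reconstruction -> LV model ->
# cartography -> colocalization.

#' Pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()], merging user
#' values over defaults. Serializes losslessly to YAML via
#' [write_config()] / [read_config()]. Every fluorescence channel is
#' reconstructed against the transmission channel at its excitation
#' wavelength; in the simulated acquisition a single intrinsic
#' transmission stack plays that role for all channels.
#'
#' @param ... named overrides of the default sections: `seed`, `phantom`
#'   (arguments of [make_lv_phantom()], or NULL to require input stacks),
#'   `angles` (`n` and `span_deg`), `artifacts` (arguments of
#'   [artifact_config()]), `recon` (arguments of [recon_config()]),
#'   `map` (`n_mu`, `n_theta`, `n_shells`), `thresholds` (`hi`, `lo`,
#'   `bead_method`), `coloc` (`max_shift`, `angles_deg`), `input`
#'   (stack paths + `lv_mask`), `output_dir`.
#' @return An `opt_config` list.
#' @export
opt_config <- function(...) {
  defaults <- list(
    seed = 1L,
    phantom = list(grid_shape = c(96L, 96L, 96L), voxel_size = 0.12),
    angles = list(n = 360L, span_deg = 360),
    artifacts = list(source_fluctuation_sd = 0, detector_gain_sd = 0,
                     noise_model = "none", noise_scale = 0),
    recon = list(filter = "shepp-logan", equalize = TRUE,
                 equalize_margin = 0.1, ring = TRUE,
                 ring_window_frac = 0.05, denoise = "none", born = TRUE),
    map = list(n_mu = 48L, n_theta = 96L, n_shells = 8L),
    thresholds = list(hi = 1.1, lo = 0.9, bead_method = "otsu"),
    coloc = list(max_shift = 4L, angles_deg = seq(-10, 10, by = 2)),
    input = NULL,
    output_dir = NULL)
  over <- list(...)
  .assert(all(nzchar(names(over) %||% character(0))) || length(over) == 0,
          "all configuration overrides must be named")
  bad <- setdiff(names(over), names(defaults))
  .assert(length(bad) == 0,
          paste("unknown configuration sections:", paste(bad, collapse = ", ")))
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[nm] <- over[nm]
    }
  }
  .assert(defaults$thresholds$hi > defaults$thresholds$lo &&
            defaults$thresholds$lo > 0, "ratio thresholds must satisfy hi > lo > 0")
  structure(defaults, class = "opt_config")
}

#' @rdname opt_config
#' @param config an `opt_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname opt_config
#' @export
read_config <- function(path) {
  .assert(file.exists(path), paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  do.call(opt_config, raw)
}

## ---- projection stack I/O ----

#' Read a multi-page TIFF projection stack
#'
#' One page per rotation angle; all pages must share shape and bit depth.
#'
#' @param path multi-page TIFF file.
#' @param angles projection angles, degrees, one per page.
#' @param channel,I0 metadata stored on the result.
#' @return An [opt_projections].
#' @export
read_projection_stack <- function(path, angles, channel = NULL, I0 = 1) {
  .assert(file.exists(path), paste("projection stack not found:", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  .assert(length(pages) == length(angles),
          sprintf("page count (%d) does not match declared angle count (%d)",
                  length(pages), length(angles)))
  bits <- vapply(pages, function(p)
    as.integer(attr(p, "bits.per.sample") %||% NA_integer_), integer(1))
  .assert(length(unique(bits[!is.na(bits)])) <= 1L,
          "mixed bit depths across pages")
  dims <- vapply(pages, dim, integer(2))
  .assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
          "pages have non-uniform frame shapes")
  frames <- array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    frames <- frames * meta$scale + meta$offset
  }
  opt_projections(frames, angles, channel = channel, I0 = I0)
}

# TIFF stores values reliably only in [0, 1]: pages are written min-max
# normalized, with the affine scale in a YAML sidecar (<path>.meta.yaml)
.write_scaled_tiff <- function(arr3, path) {
  rng <- range(arr3)
  sc <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(arr3)[3]),
                  function(k) (arr3[, , k] - rng[1]) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(offset = rng[1], scale = sc),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

.read_scaled_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(unlist(pages), c(d, length(pages)))
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    arr <- arr * meta$scale + meta$offset
  }
  arr
}

#' Write a projection stack as a 32-bit float multi-page TIFF
#'
#' Pages are min-max normalized with the affine scale kept in the TIFF
#' description tag, so arbitrary physical ranges survive the round trip.
#'
#' @param proj an [opt_projections].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_projection_stack <- function(proj, path) {
  .assert(inherits(proj, "opt_projections"), "`proj` must be opt_projections")
  .write_scaled_tiff(proj$frames, path)
}

#' Volume TIFF I/O (one page per axial slice)
#'
#' Same normalized 32-bit storage scheme as [write_projection_stack()].
#'
#' @param vol an [opt_volume].
#' @param path TIFF file path.
#' @return [read_volume_tiff()]: an [opt_volume]; writer returns `path`.
#' @export
write_volume_tiff <- function(vol, path) {
  .assert(inherits(vol, "opt_volume"), "`vol` must be opt_volume")
  .write_scaled_tiff(vol$values, path)
}

#' @rdname write_volume_tiff
#' @param path TIFF file path.
#' @param voxel_size,channel metadata for the volume read back.
#' @export
read_volume_tiff <- function(path, voxel_size, channel = NULL) {
  .assert(file.exists(path), paste("volume not found:", path))
  opt_volume(.read_scaled_tiff(path), voxel_size, channel)
}

## ---- output tree ----

#' Write the pipeline output file tree
#'
#' Volumes as 32-bit TIFF stacks, surface maps as TIFF plus delimited
#' text grids, statistics as CSV tables, and the configuration, seed and
#' provenance (config hash, package version) as YAML.
#'
#' @param results a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  .assert(ok && file.access(dir, 2) == 0,
          paste("output directory not writable:", dir))
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  for (nm in names(results$volumes)) {
    p <- file.path(dir, paste0(nm, ".tif"))
    write_volume_tiff(results$volumes[[nm]], p); add(p)
  }
  for (nm in names(results$maps)) {
    m <- results$maps[[nm]]
    v01 <- m$values
    rng <- range(v01[m$valid], na.rm = TRUE)
    utils::write.csv(m$values, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
    add(file.path(dir, paste0(nm, ".csv")))
    if (diff(rng) > 0) {
      img <- (m$values - rng[1]) / diff(rng)
      img[!m$valid | is.na(img)] <- 0
      tiff::writeTIFF(pmin(pmax(img, 0), 1),
                      file.path(dir, paste0(nm, ".tif")))
      add(file.path(dir, paste0(nm, ".tif")))
    }
  }
  for (nm in names(results$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results$tables[[nm]], p, row.names = FALSE); add(p)
  }
  cfg_path <- file.path(dir, "config.yaml")
  write_config(results$config, cfg_path); add(cfg_path)
  prov <- list(seed = results$config$seed,
               config_md5 = unname(tools::md5sum(cfg_path)),
               package_version = as.character(utils::packageVersion("optheart")),
               timings_s = results$timings)
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  add(file.path(dir, "provenance.yaml"))
  writeLines(results$log, file.path(dir, "log.txt"))
  add(file.path(dir, "log.txt"))
  invisible(written)
}

## ---- orchestration ----

#' Run the full phantom-to-colocalization pipeline
#'
#' Simulates (or loads) the acquisition, applies the sinogram correction
#' chain, reconstructs the absorption and fluorescence channels
#' (Born-normalized), fits the LV ellipsoid, renders cylindrical and
#' Bull's-Eye maps with AHA labels and probe-ratio classification,
#' delineates the infarct from the bead channel with distance-band probe
#' densities, and quantifies probe colocalization by the CCF. Stages that
#' need an LV segmentation are skipped with a notice when none is
#' available.
#'
#' @param config an [opt_config()].
#' @return A `pipeline_result` list: `volumes`, `model`, `maps`,
#'   `tables`, `coloc`, `summary`, `timings`, `log`, `config`.
#' @export
run_pipeline <- function(config = opt_config()) {
  .assert(inherits(config, "opt_config"), "`config` must be an opt_config")
  log <- character(0)
  timings <- list()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    note("stage %-12s %6.2f s", name, timings[[name]])
    out
  }

  angles <- seq(0, config$angles$span_deg, length.out = config$angles$n + 1L)
  angles <- angles[-(config$angles$n + 1L)]
  lv_mask <- NULL; endo_mask <- NULL; phantom <- NULL

  acq <- stage("acquire", {
    if (!is.null(config$phantom)) {
      phantom <- do.call(make_lv_phantom,
                          c(config$phantom, list(seed = config$seed)))
      lv_mask <- phantom$lv_mask
      endo_mask <- with(phantom, lv_mask & !myocardium_mask)
      vs <- phantom$voxel_size
      art <- do.call(artifact_config,
                     c(config$artifacts, list(seed = config$seed)))
      sim <- list(
        transmission = forward_project(phantom$absorption, angles,
                                       "transmission"),
        probe_a = forward_project(phantom$probe_a, angles, "fluorescence",
                                  absorption = phantom$absorption),
        probe_b = forward_project(phantom$probe_b, angles, "fluorescence",
                                  absorption = phantom$absorption),
        beads = forward_project(phantom$beads, angles, "fluorescence",
                                absorption = phantom$absorption))
      list(channels = lapply(sim, inject_artifacts, config = art),
           voxel_size = vs)
    } else {
      .assert(!is.null(config$input), "no phantom and no input stacks")
      vs <- config$input$voxel_size
      chans <- lapply(config$input$stacks, function(p)
        read_projection_stack(p, angles))
      if (!is.null(config$input$lv_mask))
        lv_mask <- read_volume_tiff(config$input$lv_mask, vs)$values > 0.5
      list(channels = chans, voxel_size = vs)
    }
  })
  vs <- acq$voxel_size
  rc <- do.call(recon_config, config$recon)

  volumes <- stage("reconstruct", {
    out <- list(absorption = reconstruct_volume(
      acq$channels$transmission, "absorption", voxel_size = vs, config = rc))
    for (nm in setdiff(names(acq$channels), "transmission"))
      out[[nm]] <- reconstruct_volume(
        acq$channels[[nm]], "fluorescence",
        transmission = acq$channels$transmission, voxel_size = vs,
        config = rc)
    out
  })

  if (is.null(lv_mask)) {
    note("no LV segmentation available: cartography and colocalization skipped")
    res <- list(volumes = volumes, model = NULL, maps = list(),
                tables = list(), coloc = NULL,
                summary = list(cartography = "skipped"),
                timings = timings, log = log, config = config)
    class(res) <- "pipeline_result"
    if (!is.null(config$output_dir)) write_outputs(res, config$output_dir)
    return(res)
  }

  model <- stage("lvmodel", fit_lv_ellipsoid(lv_mask, voxel_size = vs))
  grid <- map_grid(config$map$n_mu, config$map$n_theta)

  maps <- stage("cartography", {
    thick <- if (!is.null(endo_mask))
      wall_thickness(lv_mask, endo_mask, model, grid, voxel_size = vs)
    out <- list()
    if (!is.null(thick)) out$thickness <- thick
    for (nm in setdiff(names(volumes), "absorption")) {
      sh <- sample_shells(volumes[[nm]], model, config$map$n_shells, grid)
      out[[paste0(nm, "_cyl")]] <- total_projection(
        sh, thickness_map = thick, normalize = !is.null(thick))
      out[[paste0(nm, "_bullseye")]] <- bulls_eye(out[[paste0(nm, "_cyl")]])
    }
    out
  })

  tables <- list()
  coloc <- NULL
  summ <- list()

  stage("analysis", {
    labs <- aha17_labels(maps$probe_a_cyl)
    tables$aha_probe_a <- aha17_segment_stats(maps$probe_a_cyl, labs)
    tables$aha_probe_b <- aha17_segment_stats(maps$probe_b_cyl, labs)
    cls <- ratio_classify(maps$probe_a_cyl, maps$probe_b_cyl,
                          hi = config$thresholds$hi,
                          lo = config$thresholds$lo)
    keep <- .retained_nodes(maps$probe_a_cyl)
    tables$ratio_class <- as.data.frame(table(class = cls[keep]))
    summ$n_segments <- length(unique(labs[!is.na(labs)]))
    if ("beads" %in% names(volumes)) {
      myo <- if (!is.null(phantom)) phantom$myocardium_mask
        else lv_mask & !endo_mask
      inf <- infarct_mask_from_beads(volumes$beads, myo,
                                     method = config$thresholds$bead_method)
      if (!isTRUE(attr(inf, "empty"))) {
        bands <- distance_band_density(volumes$probe_a, inf, myo,
                                       voxel_size = vs)
        tables$distance_bands <- bands
        summ$band_density_ratio <- bands$density[1] / bands$density[2]
        summ$remote_fraction <- attr(bands, "remote_fraction")
      } else note("bead channel shows no hypoperfused region")
    }
    invisible(NULL)
  })

  coloc <- stage("coloc", {
    mask <- .retained_region_mask(model, dim(volumes$probe_a$values), vs)
    cc <- ccf_translational(volumes$probe_a, volumes$probe_b,
                            max_shift = config$coloc$max_shift, mask = mask)
    rot <- ccf_rotational(volumes$probe_a, volumes$probe_b, model, cc,
                          angles_deg = config$coloc$angles_deg,
                          voxel_size = vs)
    fwhm <- vapply(1:3, function(ax) as.numeric(ccf_fwhm(cc, ax)), numeric(1))
    tables$ccf <- data.frame(
      axis = c("x", "y", "z"), fwhm_voxels = fwhm, fwhm_mm = fwhm * vs)
    summ$ccf_max_r <- cc$max_r
    summ$ccf_argmax <- cc$argmax_shift
    list(translational = cc, rotational = rot, fwhm_voxels = fwhm)
  })

  res <- list(volumes = volumes, model = model, maps = maps,
              tables = tables, coloc = coloc, summary = summ,
              timings = timings, log = log, config = config,
              phantom = phantom)
  class(res) <- "pipeline_result"
  if (!is.null(config$output_dir)) write_outputs(res, config$output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  volumes:", paste(names(x$volumes), collapse = ", "), "\n")
  if (length(x$maps)) cat("  maps:   ", paste(names(x$maps), collapse = ", "), "\n")
  s <- x$summary
  if (!is.null(s$n_segments))
    cat(sprintf("  AHA segments: %d\n", s$n_segments))
  if (!is.null(s$ccf_max_r))
    cat(sprintf("  CCF max r = %.3f at shift (%s)\n", s$ccf_max_r,
                paste(s$ccf_argmax, collapse = ", ")))
  if (!is.null(s$band_density_ratio))
    cat(sprintf("  peri/remote band density ratio = %.2f, remote fraction = %.2f\n",
                s$band_density_ratio, s$remote_fraction))
  invisible(x)
}
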