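#' 3D scalar volume
#'
#' Container for reconstructed or simulated 3D scalar fields (absorption
#' maps in 1/mm, probe densities in arbitrary units, binary masks). Axial
#' slices are stacked along the third array dimension, which coincides with
#' the tomographic rotation axis (z); voxels are isotropic.
#'
#' @param values numeric or logical 3D array.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param channel optional channel identifier (e.g. `"fluor_750"`).
#' @return An object of class `opt_volume` with elements `values`,
#'   `voxel_size` and `channel`.
#' @examples
#' v <- opt_volume(array(0, c(8, 8, 8)), voxel_size = 0.1)
#' dim(v)
#' @export
opt_volume <- function(values, voxel_size, channel = NULL) {
  .assert(length(dim(values)) == 3L, "`values` must be a 3D array")
  .assert(is.numeric(voxel_size) && length(voxel_size) == 1L && voxel_size > 0,
          "`voxel_size` must be a single positive number")
  .assert(all(is.finite(values[!is.na(values)])), "`values` must be finite")
  structure(list(values = values, voxel_size = voxel_size, channel = channel),
            class = "opt_volume")
}

#' @export
dim.opt_volume <- function(x) dim(x$values)

#' @export
print.opt_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<opt_volume> %d x %d x %d voxels @ %g mm%s\n", d[1], d[2], d[3],
              x$voxel_size,
              if (is.null(x$channel)) "" else paste0(", channel ", x$channel)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# coerce opt_volume or bare array to array
.vol_values <- function(v) if (inherits(v, "opt_volume")) v$values else v

#' Single-slice sinogram
#'
#' One detector-bin-by-angle matrix for a single axial slice and channel:
#' the input domain of all sinogram-space corrections and of filtered
#' backprojection.
#'
#' @param values numeric matrix, detector bins in rows, angles in columns.
#' @param angles projection angles in degrees, strictly increasing, length
#'   `ncol(values)`, at least 8 angles.
#' @param channel,slice optional channel id and axial slice index.
#' @return An object of class `opt_sinogram`.
#' @export
opt_sinogram <- function(values, angles, channel = NULL, slice = NULL) {
  values <- as.matrix(values)
  .assert(length(angles) == ncol(values),
          "`angles` length must equal the number of sinogram columns")
  .assert(length(angles) >= 8L, "a sinogram needs at least 8 angles")
  .assert(all(diff(angles) > 0), "`angles` must be strictly increasing")
  .assert(all(is.finite(values)), "sinogram values must be finite")
  structure(list(values = values, angles = as.numeric(angles),
                 channel = channel, slice = slice),
            class = "opt_sinogram")
}

#' @export
print.opt_sinogram <- function(x, ...) {
  cat(sprintf("<opt_sinogram> %d detector bins x %d angles [%g..%g deg]%s\n",
              nrow(x$values), ncol(x$values), min(x$angles), max(x$angles),
              if (is.null(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Multi-angle projection stack
#'
#' Detector frames for one acquisition channel: a 3D array indexed
#' `[detector column (x), detector row (z), angle]`. Detector rows map
#' one-to-one onto reconstructed axial slices; detector columns are the
#' bins of each slice's sinogram.
#'
#' @param frames numeric 3D array `n_det x n_rows x n_angles`.
#' @param angles projection angles in degrees, strictly increasing.
#' @param channel optional channel identifier.
#' @param I0 nominal unobstructed source intensity for transmission frames.
#' @return An object of class `opt_projections`.
#' @export
opt_projections <- function(frames, angles, channel = NULL, I0 = 1) {
  .assert(length(dim(frames)) == 3L, "`frames` must be a 3D array")
  .assert(dim(frames)[3] == length(angles),
          "number of frames must equal number of angles")
  .assert(all(diff(angles) > 0), "`angles` must be strictly increasing")
  .assert(all(is.finite(frames)), "frames must be finite")
  structure(list(frames = frames, angles = as.numeric(angles),
                 channel = channel, I0 = I0),
            class = "opt_projections")
}

#' @export
print.opt_projections <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<opt_projections> %d x %d detector, %d angles [%g..%g deg]%s\n",
    d[1], d[2], d[3], min(x$angles), max(x$angles),
    if (is.null(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Extract one slice's sinogram from a projection stack
#'
#' @param proj an [opt_projections] object.
#' @param slice detector row index.
#' @return An [opt_sinogram] for that axial slice.
#' @export
projection_sinogram <- function(proj, slice) {
  .assert(inherits(proj, "opt_projections"), "`proj` must be opt_projections")
  d <- dim(proj$frames)
  .assert(slice >= 1 && slice <= d[2], "slice index out of range")
  opt_sinogram(proj$frames[, slice, ], proj$angles,
               channel = proj$channel, slice = slice)
}
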