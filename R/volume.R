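#' 3D intensity volume with isotropic voxel size
#'
#' A `volume3d` is a numeric 3D array of attenuation-like grayscale values
#' together with a single linear voxel edge length in micrometres. The array
#' is indexed `[z, y, x]`; the world coordinate of the centre of voxel
#' `(iz, iy, ix)` (1-based R indices) is `(ix - 1, iy - 1, iz - 1) *
#' voxel_size` micrometres, reported in `(x, y, z)` order. Nuclei and other
#' stained, protein-rich structures are stored at HIGH intensity (attenuation
#' convention); any histology-style dark-nuclei rendering is a display choice
#' only.
#'
#' @param data numeric 3D array, indexed `[z, y, x]`.
#' @param voxel_size_um linear voxel edge length in micrometres (> 0).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x) @ %.4g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

is_volume3d <- function(x) inherits(x, "volume3d")

#' Write / read a volume as a 16-bit TIFF stack with a JSON sidecar
#'
#' Slices along the first (z) axis are written as one multi-frame 16-bit
#' grayscale TIFF; intensities are min-max scaled to `[0, 1]` for storage and
#' the affine back-transform plus the voxel size are recorded in a JSON
#' sidecar (`<file>.json`) so that `read_volume_tiff()` round-trips the
#' volume to within 16-bit quantisation.
#'
#' @param vol a [volume3d()].
#' @param file output TIFF path; the sidecar is written to `paste0(file, ".json")`.
#' @return `write_volume_tiff()` returns `file` invisibly; `read_volume_tiff()`
#'   returns a [volume3d()].
#' @export
write_volume_tiff <- function(vol, file) {
  stopifnot(is_volume3d(vol))
  lo <- min(vol$data); hi <- max(vol$data)
  scale <- if (hi > lo) hi - lo else 1
  d <- dim(vol$data)
  slices <- lapply(seq_len(d[1]), function(iz) {
    (vol$data[iz, , , drop = TRUE] - lo) / scale
  })
  tiff::writeTIFF(slices, file, bits.per.sample = 16L)
  meta <- list(voxel_size_um = vol$voxel_size_um, offset = lo, scale = scale,
               shape_zyx = d, axis_order = "zyx")
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  slices <- tiff::readTIFF(file, all = TRUE)
  d <- as.integer(meta$shape_zyx)
  arr <- array(0, dim = d)
  for (iz in seq_along(slices))
    arr[iz, , ] <- slices[[iz]] * meta$scale + meta$offset
  volume3d(arr, meta$voxel_size_um)
}

# world (x,y,z) um coordinates of voxel centres for 1-based (z,y,x) indices
voxel_to_world <- function(idx_zyx, voxel_size_um) {
  idx <- as.matrix(idx_zyx)
  cbind(x = (idx[, 3] - 1) * voxel_size_um,
        y = (idx[, 2] - 1) * voxel_size_um,
        z = (idx[, 1] - 1) * voxel_size_um)
}

# containing-voxel (z,y,x) 1-based indices for world (x,y,z) um points
world_to_voxel <- function(xyz_um, voxel_size_um) {
  p <- as.matrix(xyz_um)
  cbind(round(p[, 3] / voxel_size_um) + 1,
        round(p[, 2] / voxel_size_um) + 1,
        round(p[, 1] / voxel_size_um) + 1)
}
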