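#' Assign detected nuclei to atlas regions by centroid containment
#'
#' Each centroid is assigned the label of the voxel that contains it; label 0
#' (or a centroid falling outside the grid, which triggers a warning) is
#' reported as unassigned. Counts over all regions plus unassigned always sum
#' to the number of centroids.
#'
#' @param centroids_um n x 3 matrix of `(x, y, z)` world coordinates (um) in
#'   the label map's frame.
#' @param labels a [label_map()].
#' @return list with `region` (integer per centroid, 0 = unassigned) and
#'   `counts` (named vector over the region dictionary plus `"unassigned"`).
#' @export
assign_regions <- function(centroids_um, labels) {
  stopifnot(inherits(labels, "label_map"))
  centroids_um <- as.matrix(centroids_um)
  n <- nrow(centroids_um)
  d <- dim(labels$labels)
  region <- integer(n)
  if (n > 0) {
    idx <- world_to_voxel(centroids_um, labels$voxel_size_um)
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
          idx[, 2] >= 1 & idx[, 2] <= d[2] &
          idx[, 3] >= 1 & idx[, 3] <= d[3]
    if (any(!ok))
      warning(sum(!ok), " centroid(s) outside the label grid; left unassigned")
    region[ok] <- labels$labels[idx[ok, , drop = FALSE]]
  }
  ids <- as.integer(labels$regions)
  counts <- vapply(ids, function(k) sum(region == k), integer(1))
  names(counts) <- names(labels$regions)
  counts <- c(counts, unassigned = sum(!(region %in% ids)))
  list(region = region, counts = counts)
}

#' Per-region volumes of a label map
#'
#' @param labels a [label_map()].
#' @param voxel_size_um voxel size (um); defaults to the map's own.
#' @return named numeric vector of region volumes in cubic micrometres.
#' @export
region_volumes <- function(labels, voxel_size_um = labels$voxel_size_um) {
  stopifnot(inherits(labels, "label_map"))
  ids <- as.integer(labels$regions)
  v <- vapply(ids, function(k) sum(labels$labels == k), numeric(1))
  stats::setNames(v * voxel_size_um^3, names(labels$regions))
}

#' Spherical-neighborhood cell-density map
#'
#' For every voxel inside `mask`, counts the nuclei whose centroid-containing
#' voxel lies within a Euclidean ball of `radius_voxels` voxels (the default
#' 30 voxels is ~22 um at the 0.743 um larval voxel size, about five cell
#' diameters). Balls are truncated at the volume boundary and raw counts are
#' reported (no volume normalisation) unless `normalize = TRUE`, in which
#' case counts are divided by the in-volume ball volume in cubic micrometres.
#'
#' @param centroids_um n x 3 matrix of nucleus centroids, world um.
#' @param mask logical/0-1 3D array `[z, y, x]` defining where densities are
#'   reported (e.g. the brain mask); everything outside is 0.
#' @param radius_voxels neighbourhood radius in voxels (>= 1).
#' @param voxel_size_um voxel size of the grid (um).
#' @param normalize report counts per um^3 instead of raw counts.
#' @return list with `counts` (numeric 3D array), `radius_voxels`, `mask`.
#' @export
density_map <- function(centroids_um, mask, radius_voxels = 30L,
                        voxel_size_um, normalize = FALSE) {
  if (radius_voxels < 1) stop("`radius_voxels` must be >= 1")
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  if (radius_voxels > max(d)) stop("radius exceeds every grid dimension")
  r <- as.integer(radius_voxels)
  off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  counts <- array(0, dim = d)
  centroids_um <- as.matrix(centroids_um)
  if (nrow(centroids_um) > 0) {
    ctr <- world_to_voxel(centroids_um, voxel_size_um)
    for (i in seq_len(nrow(ctr))) {
      p <- off
      p[, 1] <- p[, 1] + ctr[i, 1]
      p[, 2] <- p[, 2] + ctr[i, 2]
      p[, 3] <- p[, 3] + ctr[i, 3]
      ok <- p[, 1] >= 1 & p[, 1] <= d[1] &
            p[, 2] >= 1 & p[, 2] <= d[2] &
            p[, 3] >= 1 & p[, 3] <= d[3]
      lin <- (p[ok, 3] - 1) * d[1] * d[2] + (p[ok, 2] - 1) * d[1] + p[ok, 1]
      counts[lin] <- counts[lin] + 1
    }
  }
  counts[mask == 0] <- 0
  if (normalize) {
    ballvol <- smooth_ball_volume(d, off, voxel_size_um)
    counts <- counts / ballvol
    counts[mask == 0] <- 0
  }
  list(counts = counts, radius_voxels = r, mask = mask,
       voxel_size_um = voxel_size_um, normalized = normalize)
}

# in-volume truncated-ball volume (um^3) per voxel, for normalised densities;
# accumulated z-slab by z-slab so boundary truncation is exact
smooth_ball_volume <- function(d, off, voxel_size_um) {
  r <- max(abs(off))
  out <- array(0, dim = d)
  px <- seq_len(d[3])
  for (dz in -r:r) {
    w2 <- r^2 - dz^2
    if (w2 < 0) next
    D <- matrix(0, d[2], d[3])
    wy <- floor(sqrt(w2))
    for (dy in -wy:wy) {
      h <- floor(sqrt(w2 - dy^2))
      ox <- pmax(0, pmin(d[3], px + h) - pmax(1, px - h) + 1)
      rows <- which(seq_len(d[2]) + dy >= 1 & seq_len(d[2]) + dy <= d[2])
      D[rows, ] <- D[rows, ] + rep(ox, each = length(rows))
    }
    zz <- which(seq_len(d[1]) + dz >= 1 & seq_len(d[1]) + dz <= d[1])
    out[zz, , ] <- out[zz, , ] +
      aperm(array(D, c(d[2], d[3], length(zz))), c(3, 1, 2))
  }
  out * voxel_size_um^3
}
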