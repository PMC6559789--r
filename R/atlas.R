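#' Affine 3D transform
#'
#' World-coordinate map `p -> A p + t` with `p = (x, y, z)` in micrometres.
#'
#' @param A 3x3 matrix (non-singular for invertible use).
#' @param t length-3 translation vector (um).
#' @return object of class `affine3d`.
#' @export
affine3d <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(3, 3)), length(t) == 3, all(is.finite(A)),
            all(is.finite(t)))
  structure(list(A = A, t = as.numeric(t)), class = "affine3d")
}

#' Paired 3D landmarks
#'
#' A set of corresponding points marked in a moving and a fixed image,
#' in world micrometre coordinates `(x, y, z)`.
#'
#' @param moving,fixed n x 3 numeric matrices of paired coordinates.
#' @param names optional landmark names.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(moving, fixed, names = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3L)
    stop("`moving` and `fixed` must be n x 3 matrices of equal size")
  if (nrow(moving) < 1L) stop("at least one landmark pair is required")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("landmark coordinates must be finite")
  colnames(moving) <- colnames(fixed) <- c("x", "y", "z")
  structure(list(moving = moving, fixed = fixed, names = names),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d paired 3D landmarks (um)\n", nrow(x$moving)))
  invisible(x)
}

#' Read / write landmark pairs as CSV
#'
#' Columns: `name, mx, my, mz, fx, fy, fz` (um).
#' @param file CSV path.
#' @param l a [landmark_set()].
#' @export
read_landmarks_csv <- function(file) {
  d <- read.csv(file)
  landmark_set(as.matrix(d[, c("mx", "my", "mz")]),
               as.matrix(d[, c("fx", "fy", "fz")]),
               names = if ("name" %in% names(d)) d$name else NULL)
}

#' @rdname read_landmarks_csv
#' @export
write_landmarks_csv <- function(l, file) {
  d <- data.frame(name = if (is.null(l$names)) seq_len(nrow(l$moving)) else l$names,
                  mx = l$moving[, 1], my = l$moving[, 2], mz = l$moving[, 3],
                  fx = l$fixed[, 1], fy = l$fixed[, 2], fz = l$fixed[, 3])
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Least-squares affine fit to paired landmarks
#'
#' Finds the affine transform minimising `sum || A m_i + t - f_i ||^2` over
#' the pairs of `l`; exact when the pairs are affinely consistent.
#'
#' @param l a [landmark_set()] with >= 4 non-coplanar pairs.
#' @return an [affine3d()] mapping moving to fixed coordinates.
#' @export
fit_affine <- function(l) {
  stopifnot(inherits(l, "landmark_set"))
  n <- nrow(l$moving)
  if (n < 4L) stop("affine fit requires at least 4 landmark pairs, got ", n)
  X <- cbind(l$moving, 1)
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("degenerate landmark configuration (coplanar or coincident points): ",
         "affine fit is under-determined")
  B <- qr.coef(qrX, l$fixed)        # 4 x 3; rows: x,y,z,1 coefficients
  affine3d(t(B[1:3, , drop = FALSE]), as.numeric(B[4, ]))
}

#' Thin-plate-spline fit to paired landmarks
#'
#' Solves the standard TPS linear system per output coordinate using the 3D
#' biharmonic kernel `U(r) = r` plus an affine polynomial part, with the usual
#' polynomial side conditions. With `lambda = 0` the transform interpolates
#' every landmark exactly; increasing `lambda` smooths towards the
#' least-squares affine.
#'
#' @param l a [landmark_set()] with >= 5 pairs in general position.
#' @param lambda regularisation (>= 0).
#' @return object of class `tps3d`.
#' @export
fit_tps <- function(l, lambda = 0) {
  stopifnot(inherits(l, "landmark_set"), lambda >= 0)
  n <- nrow(l$moving)
  if (n < 5L) stop("TPS fit requires at least 5 landmark pairs, got ", n)
  if (anyDuplicated(l$moving) && lambda == 0)
    stop("duplicate moving landmarks make the unregularised TPS system singular")
  C <- l$moving
  K <- as.matrix(stats::dist(C, diag = TRUE, upper = TRUE))  # U(r) = r
  P <- cbind(1, C)
  # block elimination of the bordered system (stable for any lambda >= 0):
  # (K + lambda I) w + P a = f,  t(P) w = 0
  sol <- tryCatch({
    B <- solve(K + lambda * diag(n), cbind(l$fixed, P))
    Ff <- B[, 1:3, drop = FALSE]; Fp <- B[, 4:7, drop = FALSE]
    A <- solve(crossprod(P, Fp), crossprod(P, Ff))
    list(W = Ff - Fp %*% A, A = A)
  }, error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  structure(list(control = C, W = sol$W, A = sol$A, lambda = lambda),
            class = "tps3d")
}

#' Apply a spatial transform to points
#'
#' @param transform an [affine3d()] or a `tps3d` from [fit_tps()].
#' @param pts n x 3 matrix of `(x, y, z)` um coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, pts) UseMethod("transform_points")

#' @export
transform_points.affine3d <- function(transform, pts) {
  pts <- as.matrix(pts)
  out <- pts %*% t(transform$A)
  out <- sweep(out, 2, transform$t, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
transform_points.tps3d <- function(transform, pts) {
  pts <- as.matrix(pts)
  # evaluate in chunks to bound the n_pts x n_control distance matrix
  n <- nrow(pts)
  out <- matrix(0, n, 3)
  step <- max(1L, as.integer(2e6 / max(1L, nrow(transform$control))))
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    blk <- pts[s:e, , drop = FALSE]
    D2 <- outer(rowSums(blk^2), rowSums(transform$control^2), "+") -
      2 * blk %*% t(transform$control)
    U <- sqrt(pmax(D2, 0))
    out[s:e, ] <- cbind(1, blk) %*% transform$A + U %*% transform$W
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Integer region label map on a volume grid
#'
#' @param labels integer 3D array indexed `[z, y, x]`; 0 means background /
#'   unassigned.
#' @param voxel_size_um isotropic voxel size (um).
#' @param regions named integer vector or `id = name` dictionary; defaults to
#'   the ten larval-zebrafish brain divisions used throughout the package.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size_um, regions = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (is.null(regions)) {
    ids <- sort(unique(as.vector(labels)))
    ids <- ids[ids != 0L]
    nm <- if (length(ids) <= 9L && all(ids %in% 1:9))
      zf_brain_regions()[ids] else paste0("region_", ids)
    regions <- stats::setNames(ids, nm)
  }
  bad <- setdiff(unique(as.vector(labels)), c(0L, as.integer(regions)))
  if (length(bad))
    stop("labels present that are missing from the region dictionary: ",
         paste(bad, collapse = ", "))
  structure(list(labels = labels, voxel_size_um = voxel_size_um,
                 regions = regions),
            class = "label_map")
}

#' The ten quantifiable larval-zebrafish brain divisions
#'
#' Region dictionary used by default for brain label maps: nine named
#' divisions plus background (label 0, not listed).
#' @return named integer vector of region ids.
#' @export
zf_brain_regions <- function() {
  stats::setNames(1:9, c("Olfactory Epithelium", "Telencephalon",
                         "Diencephalon", "Hypothalamus", "Mesencephalon",
                         "Metencephalon", "Myelencephalon", "White Matter",
                         "Spinal Cord"))
}

#' Transfer a label map onto a target grid through a spatial transform
#'
#' Pull-back resampling: each target voxel centre is mapped through
#' `transform` (which must take FIXED/target world coordinates to MOVING
#' world coordinates) and assigned the nearest-neighbour label of `labels`;
#' points falling outside the moving grid become 0. Nearest-neighbour
#' sampling preserves label integrality and never invents new labels.
#'
#' @param labels a [label_map()] in the moving frame.
#' @param transform an [affine3d()] or `tps3d` mapping fixed -> moving.
#' @param target_shape integer `(z, y, x)` shape of the target grid.
#' @param voxel_size_um voxel size of the target grid (um); defaults to the
#'   moving map's.
#' @return a [label_map()] on the target grid.
#' @export
transform_labelmap <- function(labels, transform, target_shape = dim(labels$labels),
                               voxel_size_um = labels$voxel_size_um) {
  stopifnot(inherits(labels, "label_map"))
  if (!inherits(transform, "affine3d") && !inherits(transform, "tps3d"))
    stop("`transform` must map fixed (target) to moving coordinates; ",
         "fit the reverse-direction transform if you only have moving -> fixed")
  d <- as.integer(target_shape)
  g <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                             x = seq_len(d[3])))
  w <- voxel_to_world(g, voxel_size_um)
  mv <- transform_points(transform, w)
  idx <- world_to_voxel(mv, labels$voxel_size_um)
  dm <- dim(labels$labels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
        idx[, 2] >= 1 & idx[, 2] <= dm[2] &
        idx[, 3] >= 1 & idx[, 3] <= dm[3]
  out <- integer(nrow(g))
  out[ok] <- labels$labels[idx[ok, , drop = FALSE]]
  label_map(array(out, dim = d), voxel_size_um, regions = labels$regions)
}
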