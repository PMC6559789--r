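#' Voxel-feature specification
#'
#' The per-slice 2D feature bank used for voxel classification: at each
#' smoothing scale sigma (in voxels), the enabled families are Gaussian
#' smoothed intensity, gradient magnitude, Laplacian of Gaussian,
#' difference of Gaussians (sigma vs `dog_ratio * sigma`), the two structure
#' tensor eigenvalues, and the two Hessian-of-Gaussian eigenvalues.
#'
#' @param scales increasing smoothing scales, voxels.
#' @param families subset of
#'   `c("smoothed","gradient","log","dog","structure","hessian")`.
#' @param dog_ratio outer/inner scale ratio of the difference of Gaussians.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(scales = c(0.7, 1.0, 1.6, 3.5, 5.0),
                         families = c("smoothed", "gradient", "log", "dog",
                                      "structure", "hessian"),
                         dog_ratio = 1.6) {
  families <- match.arg(families, several.ok = TRUE)
  if (length(scales) < 1L || any(scales <= 0) || is.unsorted(scales))
    stop("`scales` must be positive and sorted increasing")
  if (dog_ratio <= 1) stop("`dog_ratio` must exceed 1")
  structure(list(scales = scales, families = families, dog_ratio = dog_ratio),
            class = "feature_spec")
}

n_feature_channels <- function(spec) {
  per <- c(smoothed = 1L, gradient = 1L, log = 1L, dog = 1L,
           structure = 2L, hessian = 2L)
  length(spec$scales) * sum(per[spec$families])
}

#' Per-slice 2D feature stack
#'
#' Computes one channel per (family, scale) on a 2D image with reflective
#' boundary handling; deterministic. For a full volume, features are
#' computed slice-by-slice by [classify_plane()].
#'
#' @param img numeric matrix (one slice).
#' @param spec a [feature_spec()]; the image must be at least twice the
#'   largest scale per axis.
#' @return numeric matrix `length(img) x n_channels`; column names encode
#'   family and scale.
#' @export
compute_features <- function(img, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"), is.matrix(img))
  if (min(dim(img)) < 2 * max(spec$scales))
    stop("image (", paste(dim(img), collapse = "x"),
         ") smaller than twice the largest scale")
  cols <- list()
  for (s in spec$scales) {
    sm <- gauss_filter2d(img, s, 0L, 0L)
    gx <- gauss_filter2d(img, s, 1L, 0L)
    gy <- gauss_filter2d(img, s, 0L, 1L)
    gxx <- gauss_filter2d(img, s, 2L, 0L)
    gyy <- gauss_filter2d(img, s, 0L, 2L)
    gxy <- gauss_filter2d(img, s, 1L, 1L)
    tag <- formatC(s, format = "g")
    if ("smoothed" %in% spec$families)
      cols[[paste0("smooth_", tag)]] <- as.vector(sm)
    if ("gradient" %in% spec$families)
      cols[[paste0("gradmag_", tag)]] <- as.vector(sqrt(gx^2 + gy^2))
    if ("log" %in% spec$families)
      cols[[paste0("log_", tag)]] <- as.vector(gxx + gyy)
    if ("dog" %in% spec$families)
      cols[[paste0("dog_", tag)]] <-
        as.vector(sm - gauss_filter2d(img, s * spec$dog_ratio, 0L, 0L))
    if ("structure" %in% spec$families) {
      # structure tensor smoothed at the same (outer) scale
      j11 <- gauss_filter2d(gx * gx, s, 0L, 0L)
      j22 <- gauss_filter2d(gy * gy, s, 0L, 0L)
      j12 <- gauss_filter2d(gx * gy, s, 0L, 0L)
      tr <- j11 + j22
      disc <- sqrt(pmax((j11 - j22)^2 + 4 * j12^2, 0))
      cols[[paste0("st_hi_", tag)]] <- as.vector((tr + disc) / 2)
      cols[[paste0("st_lo_", tag)]] <- as.vector((tr - disc) / 2)
    }
    if ("hessian" %in% spec$families) {
      tr <- gxx + gyy
      disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
      cols[[paste0("hess_hi_", tag)]] <- as.vector((tr + disc) / 2)
      cols[[paste0("hess_lo_", tag)]] <- as.vector((tr - disc) / 2)
    }
  }
  do.call(cbind, cols)
}
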