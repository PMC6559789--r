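#' Volume of a segmented object
#'
#' Voxel count times the cubic voxel volume.
#'
#' @param voxels integer matrix of voxel indices (columns z, y, x) or a
#'   `nucleus_set` row's voxel set.
#' @param voxel_size_um linear voxel size, um.
#' @return volume in cubic micrometres.
#' @export
object_volume <- function(voxels, voxel_size_um) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0L) stop("empty voxel set has no volume")
  nrow(voxels) * voxel_size_um^3
}

#' Moment-based elongation of a 3D object
#'
#' Ratio of the longest to the shortest principal axis: the 3x3 second
#' central moment matrix of the voxel coordinates is eigen-decomposed, axis
#' lengths are proportional to the square roots of its eigenvalues, and the
#' ratio `sqrt(lambda_max / lambda_min)` is returned. A sphere gives 1; a
#' single-voxel object returns exactly 1; a degenerate (coplanar/collinear)
#' voxel set returns `Inf`. The measure is invariant to rotation and to
#' uniform scaling of the coordinates.
#'
#' @param voxels integer matrix of voxel indices (columns z, y, x).
#' @return elongation ratio `>= 1`.
#' @export
elongation <- function(voxels) {
  voxels <- as.matrix(voxels)
  n <- nrow(voxels)
  if (n == 0L) stop("empty voxel set has no elongation")
  if (n == 1L) return(1)
  M <- stats::cov(voxels) * (n - 1) / n   # second central moments
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev)) return(Inf)
  sqrt(max(ev) / min(ev))
}

# principal axis lengths (um): 2*sqrt(5*lambda) of a solid ellipsoid's moments
principal_axes_um <- function(voxels, voxel_size_um) {
  voxels <- as.matrix(voxels)
  n <- nrow(voxels)
  if (n < 2L) return(rep(voxel_size_um, 3))
  M <- stats::cov(voxels) * (n - 1) / n
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  2 * sqrt(5 * pmax(ev, 0)) * voxel_size_um
}

#' Per-class shape summary of a set of objects
#'
#' Means, SDs and histogram-ready distributions of volume and elongation for
#' objects grouped by cell class.
#'
#' @param voxel_sets list of voxel index matrices (columns z, y, x).
#' @param class character/factor of the same length assigning each object to
#'   a class; every class must be non-empty.
#' @param voxel_size_um linear voxel size, um.
#' @return list with `table` (data.frame: class, n, mean_volume_um3,
#'   sd_volume_um3, mean_elongation, sd_elongation) and `objects` (per-object
#'   data.frame with class, volume and elongation).
#' @export
cohort_shape_summary <- function(voxel_sets, class, voxel_size_um) {
  if (length(voxel_sets) == 0L) stop("no objects supplied")
  if (length(class) != length(voxel_sets))
    stop("`class` must label every object")
  class <- as.character(class)
  if (any(table(class) == 0)) stop("empty class")
  vols <- vapply(voxel_sets, object_volume, numeric(1),
                 voxel_size_um = voxel_size_um)
  elo <- vapply(voxel_sets, elongation, numeric(1))
  objects <- data.frame(class = class, volume_um3 = vols, elongation = elo)
  agg <- do.call(rbind, lapply(split(objects, objects$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d),
               mean_volume_um3 = mean(d$volume_um3),
               sd_volume_um3 = if (nrow(d) > 1) sd(d$volume_um3) else NA_real_,
               mean_elongation = mean(d$elongation),
               sd_elongation = if (nrow(d) > 1) sd(d$elongation) else NA_real_)
  }))
  rownames(agg) <- NULL
  list(table = agg, objects = objects)
}

# moving-average detrend; window forced odd, clamped to profile length
detrend_profile <- function(x, window) {
  n <- length(x)
  window <- min(max(3L, as.integer(window)), if (n %% 2L) n else n - 1L)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  base <- stats::filter(xp, rep(1 / window, window), sides = 2)
  x - as.numeric(base[(half + 1):(half + n)])
}

#' Dominant period of a 1D line profile
#'
#' The profile is detrended by subtracting a moving-average baseline
#' (window about three times the longest expected period), its lag
#' autocorrelation (normalised, `1/(n-k)` scaling to avoid taper bias) is
#' scanned for the first local maximum, and the peak location is refined to
#' sub-sample precision by parabolic interpolation before conversion to
#' micrometres. Used e.g. to measure the spacing of skeletal-muscle
#' striations as an internal resolution check.
#'
#' @param profile numeric vector of samples along a line.
#' @param voxel_size_um sample spacing, um.
#' @param max_period_vox longest period (in samples) the detrender should
#'   preserve; defaults to a quarter of the profile length.
#' @param min_peak minimum autocorrelation a candidate peak must reach.
#' @return period in micrometres.
#' @export
profile_period <- function(profile, voxel_size_um,
                           max_period_vox = length(profile) %/% 4,
                           min_peak = 0.2) {
  n <- length(profile)
  if (n < 8L) stop("profile too short for period estimation")
  x <- detrend_profile(profile, 3L * max_period_vox)
  if (sd(x) == 0) stop("no period detected: constant profile")
  x <- x - mean(x)
  kmax <- min(n - 2L, 3L * max_period_vox)
  denom <- sum(x^2) / n
  r <- vapply(0:kmax, function(k) {
    m <- n - k
    sum(x[1:m] * x[(k + 1):n]) / m / denom
  }, numeric(1))
  # first local max after the zero-lag peak; the period is expected to be at
  # most max_period_vox, so longer lags are not searched (their 1/(n-k)
  # normalisation also inflates noise)
  peak <- NA_integer_
  for (k in 2:min(kmax - 1L, max_period_vox + 2L)) {
    if (r[k + 1] >= r[k] && r[k + 1] > r[k + 2] && r[k + 1] >= min_peak) {
      peak <- k
      break
    }
  }
  if (is.na(peak)) stop("no period detected: no secondary autocorrelation peak")
  refine <- function(k) {   # parabolic sub-sample refinement around lag k
    ym <- r[k]; y0 <- r[k + 1]; yp <- r[k + 2]
    d <- if (ym - 2 * y0 + yp < 0) 0.5 * (ym - yp) / (ym - 2 * y0 + yp) else 0
    k + d
  }
  per <- refine(peak)
  # sharpen by climbing to higher-order peaks: the sub-sample error at lag
  # ~ j*P is divided by the cycle count j, and each step re-estimates P so
  # the next prediction stays within half a period of the true peak
  lag_cap <- min(kmax - 2L, n %/% 2L)
  j <- 1L
  repeat {
    jn <- min(floor(lag_cap / per), j * 4L)
    if (jn <= j) break
    target <- round(jn * per)
    win <- max(2L, floor(per / 2))
    lo <- max(2L, target - win); hi <- min(kmax - 1L, target + win)
    kk <- lo:hi
    kbest <- kk[which.max(r[kk + 1L])]
    if (!(kbest > lo && kbest < hi) || r[kbest + 1L] < min_peak / 2) break
    jfound <- round(kbest / per)
    if (jfound < 1L) break
    per <- refine(kbest) / jfound
    j <- jn
  }
  per * voxel_size_um
}

#' Modulation depth of a line profile
#'
#' After moving-average detrending, the profile is shifted back up by its
#' original mean and the Michelson-style depth `(max - min) / (max + min)`
#' is returned: 0 for a constant profile, `a / m` for a sinusoid of
#' amplitude `a` about a mean `m > a`. Used to score phase-contrast edge
#' enhancement from line profiles across periodic structures.
#'
#' @inheritParams profile_period
#' @return modulation depth in `[0, 1]`.
#' @export
modulation_depth <- function(profile, max_period_vox = length(profile) %/% 4) {
  n <- length(profile)
  m <- mean(profile)
  x <- detrend_profile(profile, 3L * max_period_vox) + m
  # evaluate extrema only where the moving-average window is fully supported,
  # avoiding baseline distortion at the profile ends
  w <- min(3L * max_period_vox, n)
  half <- (w - 1L) %/% 2L
  if (n - 2L * half >= 8L) x <- x[(half + 1L):(n - half)]
  if (max(x) + min(x) <= 0)
    stop("non-positive profile mean after detrending; depth undefined")
  (max(x) - min(x)) / (max(x) + min(x))
}
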