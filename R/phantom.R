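#' Specification of a synthetic histotomography phantom
#'
#' Describes a synthetic volume that emulates a PTA-stained larval-zebrafish
#' acquisition: ellipsoidal high-attenuation nuclei of one or more cell
#' classes scattered without overlap in a smoothly textured background, with
#' additive Gaussian noise and an optional phase-contrast-like edge halo.
#' Defaults emulate crowded brain tissue at the larval acquisition scale:
#' 0.743 um isotropic voxels and near-spherical nuclei of ~13 um^3.
#'
#' @param shape integer vector of 3 voxel counts `(z, y, x)`, each >= 16.
#' @param voxel_size_um linear voxel size in micrometres.
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param semi_axes_dist range `c(min, max)` in micrometres from which each
#'   nucleus's two minor semi-axes are drawn (must be >= 1 voxel).
#' @param target_elongation named or unnamed numeric vector of major/minor
#'   axis ratios, one per cell class; a class is drawn uniformly per nucleus.
#' @param nucleus_contrast intensity offset of nucleus voxels above the local
#'   background (arbitrary attenuation units).
#' @param background_level mean background intensity.
#' @param background_texture_scale correlation length (um) of the smooth
#'   background field; 0 disables texture.
#' @param texture_amplitude standard deviation of the background texture field.
#' @param noise_sigma SD of additive Gaussian voxel noise.
#' @param halo_strength amplitude of the signed edge-enhancement ring added at
#'   nucleus boundaries (0 disables; mimics propagation phase-contrast fringes).
#' @param min_separation_um minimum surface-to-surface distance between nuclei.
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L),
                         voxel_size_um = 0.743,
                         n_nuclei = 500L,
                         semi_axes_dist = c(1.1, 1.6),
                         target_elongation = c(brain = 1.1),
                         nucleus_contrast = 60,
                         background_level = 100,
                         background_texture_scale = 6,
                         texture_amplitude = 6,
                         noise_sigma = 12,
                         halo_strength = 0,
                         min_separation_um = 1.5,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("`shape` must be 3 integers, each >= 16")
  if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
  if (n_nuclei < 0) stop("`n_nuclei` must be >= 0")
  if (length(semi_axes_dist) != 2L || diff(semi_axes_dist) < 0)
    stop("`semi_axes_dist` must be c(min, max)")
  if (semi_axes_dist[1] < voxel_size_um)
    stop("minimum semi-axis must be at least one voxel")
  if (any(target_elongation < 1)) stop("elongation ratios must be >= 1")
  if (noise_sigma < 0 || texture_amplitude < 0 || min_separation_um < 0)
    stop("noise, texture and separation parameters must be >= 0")
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 semi_axes_dist = as.numeric(semi_axes_dist),
                 target_elongation = target_elongation,
                 nucleus_contrast = nucleus_contrast,
                 background_level = background_level,
                 background_texture_scale = background_texture_scale,
                 texture_amplitude = texture_amplitude,
                 noise_sigma = noise_sigma, halo_strength = halo_strength,
                 min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

random_rotation <- function() {
  # uniform random 3D rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a nuclei phantom with voxel-level ground truth
#'
#' Places `n_nuclei` randomly oriented ellipsoids (no two overlapping; surface
#' separation at least `min_separation_um`) by bounded dart throwing, then
#' rasterises them at `nucleus_contrast` above a textured background, adds an
#' optional edge halo and Gaussian noise. The returned ground truth records,
#' per nucleus, its analytic centroid (um, world coordinates), its voxel set,
#' its cell class and semi-axes.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [volume3d()]) and `truth`, a
#'   `ground_truth` object: list with `centroids_um` (n x 3 matrix, x/y/z),
#'   `voxels` (list of n integer matrices with columns z,y,x, 1-based),
#'   `class` (character), `region` (integer, NA until an atlas is attached)
#'   and `semi_axes_um` (n x 3).
#' @export
generate_nuclei_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_nuclei_phantom_impl(spec))
}

generate_nuclei_phantom_impl <- function(spec) {
  d <- spec$shape
  vs <- spec$voxel_size_um
  n <- spec$n_nuclei
  classes <- names(spec$target_elongation)
  if (is.null(classes)) classes <- as.character(seq_along(spec$target_elongation))

  # --- sample nucleus geometry -------------------------------------------
  cls_idx <- if (n > 0) sample.int(length(spec$target_elongation), n, replace = TRUE) else integer()
  minor <- runif(n, spec$semi_axes_dist[1], spec$semi_axes_dist[2])
  major <- minor * spec$target_elongation[cls_idx]
  axes <- cbind(a = major, b = minor, c = minor)   # um
  rots <- lapply(seq_len(n), function(i) random_rotation())

  # --- dart-throwing placement (centres in 0-based voxel units, z,y,x) ----
  centers <- matrix(0, n, 3)
  reach_vox <- major / vs + 1           # bounding radius incl. rasterisation margin
  max_attempts <- 100L * max(n, 1L)
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("overcrowded spec: could not place ", n, " nuclei with min_separation ",
           spec$min_separation_um, " um after ", max_attempts, " attempts")
    i <- placed + 1L
    m <- reach_vox[i]
    if (any(d - 1 - 2 * m <= 0))
      stop("overcrowded spec: nucleus larger than volume interior")
    cand <- c(runif(1, m, d[1] - 1 - m),
              runif(1, m, d[2] - 1 - m),
              runif(1, m, d[3] - 1 - m))
    ok <- TRUE
    if (placed > 0L) {
      dv <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2)) * vs
      need <- major[seq_len(placed)] + major[i] + spec$min_separation_um
      ok <- all(dv >= need)
    }
    if (ok) {
      centers[i, ] <- cand
      placed <- i
    }
  }

  # --- background field ---------------------------------------------------
  vol <- array(spec$background_level, dim = d)
  if (spec$texture_amplitude > 0 && spec$background_texture_scale > 0) {
    tex <- array(rnorm(prod(d)), dim = d)
    tex <- smooth3d(tex, spec$background_texture_scale / vs)
    tex <- (tex - mean(tex)) / sd(tex) * spec$texture_amplitude
    vol <- vol + tex
  }

  # --- rasterise ellipsoids ----------------------------------------------
  voxels <- vector("list", n)
  for (i in seq_len(n)) {
    ctr <- centers[i, ]
    r <- reach_vox[i]
    zr <- max(1L, floor(ctr[1] - r) + 1L):min(d[1], ceiling(ctr[1] + r) + 1L)
    yr <- max(1L, floor(ctr[2] - r) + 1L):min(d[2], ceiling(ctr[2] + r) + 1L)
    xr <- max(1L, floor(ctr[3] - r) + 1L):min(d[3], ceiling(ctr[3] + r) + 1L)
    g <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
    u <- (t(g) - 1 - ctr) * vs                      # 3 x m, um offsets (z,y,x)
    # rotate into the ellipsoid frame; rotation acts on (x,y,z) ordering
    uxyz <- u[c(3, 2, 1), , drop = FALSE]
    v <- t(rots[[i]]) %*% uxyz
    inside <- colSums((v / axes[i, ])^2) <= 1
    sel <- g[inside, , drop = FALSE]
    voxels[[i]] <- sel
    vol[sel] <- vol[sel] + spec$nucleus_contrast
  }

  # --- halo and noise -----------------------------------------------------
  if (spec$halo_strength > 0 && n > 0) {
    mask <- array(0, dim = d)
    for (i in seq_len(n)) mask[voxels[[i]]] <- 1
    vol <- vol + spec$halo_strength * (smooth3d(mask, 1) - smooth3d(mask, 2))
  }
  if (spec$noise_sigma > 0)
    vol <- vol + array(rnorm(prod(d), 0, spec$noise_sigma), dim = d)

  centroids <- if (n > 0)
    cbind(x = centers[, 3] * vs, y = centers[, 2] * vs, z = centers[, 1] * vs)
  else matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z")))

  truth <- structure(list(centroids_um = centroids, voxels = voxels,
                          class = classes[cls_idx],
                          region = rep(NA_integer_, n),
                          semi_axes_um = axes,
                          voxel_size_um = vs, shape = d),
                     class = "ground_truth")
  list(volume = volume3d(vol, vs), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei in %d x %d x %d grid @ %.4g um\n",
              nrow(x$centroids_um), x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_um))
  invisible(x)
}

#' Generate a striated-muscle phantom
#'
#' A sinusoidal band pattern of known spatial period along the x axis (third
#' array dimension), emulating the periodic cross-striations of skeletal
#' muscle fibres used as an internal resolution check.
#'
#' @param period_um pattern period in micrometres; must satisfy the Nyquist
#'   bound `period_um >= 2 * voxel_size_um`.
#' @param voxel_size_um isotropic voxel size (um).
#' @param noise_sigma additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param shape volume shape `(z, y, x)`; the pattern runs along x.
#' @param amplitude,offset sinusoid amplitude and mean level.
#' @param phase phase at x = 0, radians.
#' @return A [volume3d()].
#' @export
generate_striation_phantom <- function(period_um, voxel_size_um, noise_sigma = 0,
                                       seed = 1L, shape = c(16L, 16L, 256L),
                                       amplitude = 30, offset = 100, phase = 0) {
  if (period_um < 2 * voxel_size_um)
    stop("period (", period_um, " um) below the Nyquist bound 2 * voxel size (",
         2 * voxel_size_um, " um)")
  shape <- as.integer(shape)
  with_seed(seed, {
    x_um <- (seq_len(shape[3]) - 1) * voxel_size_um
    prof <- offset + amplitude * sin(2 * pi * x_um / period_um + phase)
    vol <- array(rep(prof, each = shape[1] * shape[2]), dim = shape)
    if (noise_sigma > 0)
      vol <- vol + array(rnorm(prod(shape), 0, noise_sigma), dim = shape)
    volume3d(vol, voxel_size_um)
  })
}

#' Generate an atlas-registration phantom
#'
#' Builds a nuclei phantom together with a "fixed" multi-region label map (an
#' ellipsoidal brain-like mask partitioned into `n_regions` Voronoi regions),
#' a "moving" label map related to it by a known invertible affine warp, and
#' paired landmarks sampled on region boundaries. Ground-truth `region` ids
#' are assigned from the unwarped (fixed) labels.
#'
#' @param spec a [phantom_spec()].
#' @param n_regions number of atlas regions (>= 2).
#' @param warp an [affine3d()] mapping fixed world coordinates (um) to moving
#'   world coordinates; must be invertible.
#' @param n_landmarks number of boundary landmark pairs (>= 8).
#' @return list with `volume`, `truth` (regions filled in), `fixed_labels` and
#'   `moving_labels` ([label_map()]s), and `landmarks` (a [landmark_set()]
#'   with moving/fixed pairs).
#' @export
generate_atlas_phantom <- function(spec, n_regions = 9L, warp = affine3d(),
                                   n_landmarks = 12L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_regions < 2) stop("`n_regions` must be >= 2")
  if (n_landmarks < 8) stop("at least 8 landmark pairs are required")
  Ainv <- tryCatch(solve(warp$A), error = function(e)
    stop("warp is not invertible on the grid"))
  ph <- generate_nuclei_phantom(spec)
  d <- spec$shape; vs <- spec$voxel_size_um

  with_seed(spec$seed + 1L, {
    # ellipsoidal mask partitioned by nearest region seed
    ctr <- (d - 1) / 2
    g <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                               x = seq_len(d[3])))
    rel <- sweep(g - 1, 2, ctr, "-")
    rel <- sweep(rel, 2, pmax(ctr, 1), "/")
    inside <- rowSums(rel^2) <= 0.95^2
    seeds <- g[sample(which(inside), n_regions), , drop = FALSE]
    lab <- integer(nrow(g))
    ins <- which(inside)
    dmat <- matrix(0, length(ins), n_regions)
    for (k in seq_len(n_regions))
      dmat[, k] <- colSums((t(g[ins, , drop = FALSE]) - seeds[k, ])^2)
    lab[ins] <- max.col(-dmat, ties.method = "first")
    fixed <- label_map(array(lab, dim = d), vs)

    # truth regions from fixed labels at centroid-containing voxels
    if (nrow(ph$truth$centroids_um) > 0) {
      idx <- world_to_voxel(ph$truth$centroids_um, vs)
      ph$truth$region <- fixed$labels[idx]
    }

    # moving map: pull fixed labels through the inverse warp
    tw <- voxel_to_world(g, vs)                       # (x,y,z) um
    back <- transform_points(affine3d(Ainv, -as.vector(Ainv %*% warp$t)), tw)
    bidx <- world_to_voxel(back, vs)
    okb <- bidx[, 1] >= 1 & bidx[, 1] <= d[1] &
           bidx[, 2] >= 1 & bidx[, 2] <= d[2] &
           bidx[, 3] >= 1 & bidx[, 3] <= d[3]
    mlab <- integer(nrow(g))
    mlab[okb] <- fixed$labels[bidx[okb, , drop = FALSE]]
    moving <- label_map(array(mlab, dim = d), vs, regions = fixed$regions)

    # boundary landmarks: voxels whose +z/+y/+x neighbour carries another label
    la <- fixed$labels
    bnd <- which((la != 0) & (
      (abind_shift(la, 1) != la) | (abind_shift(la, 2) != la) |
      (abind_shift(la, 3) != la)))
    bsel <- bnd[round(seq(1, length(bnd), length.out = n_landmarks))]
    bidx2 <- arrayInd(bsel, d)
    f_pts <- voxel_to_world(bidx2, vs)
    m_pts <- transform_points(warp, f_pts)
    lms <- landmark_set(moving = m_pts, fixed = f_pts)

    list(volume = ph$volume, truth = ph$truth, fixed_labels = fixed,
         moving_labels = moving, landmarks = lms)
  })
}

# shift an array by one voxel along `axis` (edge replicated); internal
abind_shift <- function(a, axis) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(idx[[axis]] + 1L, d[axis])
  do.call(`[`, c(list(a), idx))
}

#' Generate a cohort of phantoms with per-specimen density multipliers
#'
#' Emulates inter-specimen variation in cell density: specimen `i` receives an
#' expected nucleus count of `density_offsets[i] * base$n_nuclei` (binomial
#' thinning for multipliers <= 1, Poisson super-sampling above 1), with
#' per-specimen seeds derived deterministically from the base seed.
#'
#' @param n_specimens number of specimens (>= 1).
#' @param density_offsets positive multiplier(s), recycled to `n_specimens`.
#' @param base a [phantom_spec()] shared by the cohort.
#' @return list of `n_specimens` elements, each a list with `volume`, `truth`.
#' @export
generate_cohort <- function(n_specimens, density_offsets = 1, base = phantom_spec()) {
  if (n_specimens < 1) stop("`n_specimens` must be >= 1")
  m <- rep_len(density_offsets, n_specimens)
  if (any(m <= 0)) stop("density multipliers must be positive")
  lapply(seq_len(n_specimens), function(i) {
    seed_i <- as.integer((as.double(base$seed) * 10007 + i) %% 2147483647)
    n_i <- with_seed(seed_i, {
      if (m[i] <= 1) rbinom(1L, base$n_nuclei, m[i])
      else rpois(1L, base$n_nuclei * m[i])
    })
    spec_i <- base
    spec_i$n_nuclei <- n_i
    spec_i$seed <- seed_i + 1L
    generate_nuclei_phantom(spec_i)
  })
}
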