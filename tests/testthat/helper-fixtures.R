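# Shared fixtures, built once per test run.

# small, clean phantom used by several modules (no noise/texture)
clean_spec <- function(n = 40L, seed = 3L)
  phantom_spec(shape = c(48L, 48L, 48L), n_nuclei = n, noise_sigma = 0,
               texture_amplitude = 0, seed = seed)

tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_nuclei_phantom(
        phantom_spec(shape = c(48L, 48L, 48L), n_nuclei = 40L, seed = 5L))
    cache
  }
})

# rasterise an axis-aligned ellipsoid: voxel centres inside
# sum((p/semi_axes)^2) <= 1, returned as 1-based (z,y,x) indices
rasterize_ellipsoid <- function(semi_axes_vox, pad = 3L) {
  r <- ceiling(max(semi_axes_vox)) + pad
  g <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))
  # expand.grid columns are (z,y,x); semi_axes given as (a_z, a_y, a_x)
  inside <- rowSums(sweep(g, 2, semi_axes_vox, "/")^2) <= 1
  g[inside, , drop = FALSE] + r + 1L
}

# brute-force ball-count oracle: per voxel, count centroids within radius
brute_force_density <- function(centers_vox, d, radius) {
  out <- array(0, dim = d)
  for (i in seq_len(nrow(centers_vox))) {
    dz2 <- (seq_len(d[1]) - centers_vox[i, 1])^2
    dy2 <- (seq_len(d[2]) - centers_vox[i, 2])^2
    dx2 <- (seq_len(d[3]) - centers_vox[i, 3])^2
    out <- out + (outer(outer(dz2, dy2, "+"), dx2, "+") <= radius^2)
  }
  out
}
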