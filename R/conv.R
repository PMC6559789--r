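# Internal separable Gaussian filtering with symmetric boundary reflection.
# Kernels are sampled derivatives of the Gaussian, renormalised so that the
# order-0 kernel has unit sum, the order-1 kernel has unit response to a
# unit-slope ramp and the order-2 kernel unit response to x^2/2.

gauss_kernel1d <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- x * g                 # correlation kernel: response to ramp x is slope
    k <- k - mean(k)
    k / sum(x * k)
  } else {
    k <- (x^2 / sigma^2 - 1) * g
    k <- k - mean(k)           # zero DC response
    k / sum(x^2 * k / 2)
  }
}

# correlate along dim 1 of a matrix, symmetric (edge-repeating) reflection
conv_dim1 <- function(X, k) {
  n <- nrow(X)
  r <- (length(k) - 1L) %/% 2L
  if (2L * r + 1L > 2L * n)
    stop("image extent (", n, ") too small for kernel support (", 2 * r + 1, ")")
  idx <- c(rev(seq_len(r)), seq_len(n), n:(n - r + 1L))
  Xp <- X[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(X))
  for (i in seq_along(k))
    out <- out + k[i] * Xp[i:(i + n - 1L), , drop = FALSE]
  out
}

# 2D Gaussian-derivative filter: order along rows (dim 1) and columns (dim 2)
gauss_filter2d <- function(img, sigma, order1 = 0L, order2 = 0L) {
  k1 <- gauss_kernel1d(sigma, order1)
  k2 <- gauss_kernel1d(sigma, order2)
  t(conv_dim1(t(conv_dim1(img, k1)), k2))
}

# isotropic 3D Gaussian smoothing (order 0) of an array, sigma in voxels
smooth3d <- function(arr, sigma) {
  d <- dim(arr)
  k <- gauss_kernel1d(sigma, 0L)
  a <- matrix(arr, d[1], d[2] * d[3])
  a <- array(conv_dim1(a, k), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(conv_dim1(matrix(a, d[2], d[1] * d[3]), k), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(conv_dim1(matrix(a, d[3], d[2] * d[1]), k), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

# run code with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
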