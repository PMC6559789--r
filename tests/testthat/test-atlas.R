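random_landmarks <- function(n = 8, seed = 2, A = NULL, tr = c(5, -3, 2)) {
  set.seed(seed)
  if (is.null(A)) A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  m <- matrix(runif(3 * n, 0, 60), n, 3)
  f <- m %*% t(A) + matrix(tr, n, 3, byrow = TRUE)
  list(l = landmark_set(m, f), A = A, t = tr)
}

test_that("affine fit recovers identity and known transforms exactly", {
  m <- matrix(runif(24, 0, 50), 8, 3)
  fit0 <- fit_affine(landmark_set(m, m))
  expect_lt(max(abs(fit0$A - diag(3))), 1e-10)
  expect_lt(max(abs(fit0$t)), 1e-10)
  rl <- random_landmarks()
  fit <- fit_affine(rl$l)
  expect_lt(max(abs(fit$A - rl$A)), 1e-8)
  expect_lt(max(abs(fit$t - rl$t)), 1e-8)
  # coplanar points are rejected
  cop <- cbind(matrix(runif(8, 0, 10), 4, 2), 0)
  expect_error(fit_affine(landmark_set(cop, cop)), "degenerate")
  expect_error(fit_affine(landmark_set(m[1:3, ], m[1:3, ])), "at least 4")
})

test_that("TPS interpolates landmarks exactly at lambda = 0", {
  rl <- random_landmarks(n = 10, seed = 4)
  # bend the target points so the map is genuinely non-affine
  f <- rl$l$fixed + 0.5 * sin(rl$l$moving / 10)
  l <- landmark_set(rl$l$moving, f)
  tp <- fit_tps(l, lambda = 0)
  expect_lt(max(abs(transform_points(tp, l$moving) - f)), 1e-6)
  dup <- landmark_set(l$moving[c(1, 1, 2:5), ], f[1:6, ])
  expect_error(fit_tps(dup, 0), "singular|duplicate")
  expect_error(fit_tps(landmark_set(l$moving[1:4, ], f[1:4, ])), "at least 5")
})

test_that("TPS reproduces an affine map and tends to it as lambda grows", {
  rl <- random_landmarks(n = 9, seed = 6)
  tp <- fit_tps(rl$l, 0)
  expect_lt(max(abs(tp$W)), 1e-8)      # kernel silent on affine data
  set.seed(8)
  probe <- matrix(runif(30, 5, 55), 10, 3)
  want <- probe %*% t(rl$A) + matrix(rl$t, 10, 3, byrow = TRUE)
  expect_lt(max(abs(transform_points(tp, probe) - want)), 1e-7)
  # strong regularisation collapses a bent map onto the least-squares affine
  f_bent <- rl$l$fixed + 2 * sin(rl$l$moving / 8)
  lb <- landmark_set(rl$l$moving, f_bent)
  tp_stiff <- fit_tps(lb, lambda = 1e8)
  aff <- fit_affine(lb)
  expect_lt(max(abs(transform_points(tp_stiff, probe) -
                      transform_points(aff, probe))), 1e-2)
})

test_that("label transfer is exact for identity and integer translations", {
  set.seed(10)
  lab <- array(sample(0:3, 20^3, replace = TRUE), dim = c(20, 20, 20))
  lm <- label_map(lab, 1, regions = stats::setNames(1:3, c("a", "b", "c")))
  idt <- transform_labelmap(lm, affine3d(), c(20, 20, 20))
  expect_identical(idt$labels, lm$labels)
  expect_identical(idt$regions, lm$regions)
  # fixed -> moving shift by +2 voxels in x: labels move by -2
  tr <- transform_labelmap(lm, affine3d(diag(3), c(2, 0, 0)), c(20, 20, 20))
  expect_identical(tr$labels[, , 1:18], lm$labels[, , 3:20])
  expect_true(all(tr$labels[, , 19:20] == 0L))
  # no labels invented
  expect_true(all(unique(as.vector(tr$labels)) %in% c(0L, 1L, 2L, 3L)))
})

test_that("warp and unwarp round-trips phantom labels away from boundaries", {
  sp <- phantom_spec(shape = c(48L, 48L, 48L), n_nuclei = 15L, seed = 23L)
  A <- diag(3) * 1.02
  A[1, 2] <- 0.03
  warp <- affine3d(A, c(1.3, -0.9, 0.7))
  ap <- generate_atlas_phantom(sp, n_regions = 5L, warp = warp)
  back <- transform_labelmap(ap$moving_labels, warp,
                             dim(ap$fixed_labels$labels))
  # compare on the eroded interior: voxels whose 6-neighbourhood is one label
  la <- ap$fixed_labels$labels
  d <- dim(la)
  interior <- array(TRUE, d)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  same6 <- interior
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  same6[ii, jj, kk] <-
    la[ii - 1, jj, kk] == la[ii, jj, kk] & la[ii + 1, jj, kk] == la[ii, jj, kk] &
    la[ii, jj - 1, kk] == la[ii, jj, kk] & la[ii, jj + 1, kk] == la[ii, jj, kk] &
    la[ii, jj, kk - 1] == la[ii, jj, kk] & la[ii, jj, kk + 1] == la[ii, jj, kk]
  core <- interior & same6 & la != 0
  expect_gt(mean(back$labels[core] == la[core]), 0.99)
})

test_that("region assignment by centroid containment is exact on the phantom", {
  sp <- phantom_spec(shape = c(48L, 48L, 48L), n_nuclei = 25L, seed = 29L)
  ap <- generate_atlas_phantom(sp, n_regions = 4L)
  asg <- assign_regions(ap$truth$centroids_um, ap$fixed_labels)
  expect_equal(asg$region, ap$truth$region)
  expect_equal(sum(asg$counts), nrow(ap$truth$centroids_um))
  # a centroid far outside the grid is unassigned, with a warning
  expect_warning(
    out <- assign_regions(rbind(ap$truth$centroids_um, c(900, 900, 900)),
                          ap$fixed_labels),
    "outside")
  expect_equal(out$region[length(out$region)], 0L)
})

test_that("region volumes partition the labelled volume", {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[1:5, , ] <- 1L; lab[6:8, , ] <- 2L
  lm <- label_map(lab, 2, regions = stats::setNames(1:2, c("a", "b")))
  rv <- region_volumes(lm)
  expect_equal(unname(rv), c(500, 300) * 8)
  expect_equal(sum(rv), sum(lab != 0) * 8)
  expect_equal(unname(region_volumes(lm, voxel_size_um = 1)), c(500, 300))
})

test_that("density map equals brute-force ball counting and is linear", {
  set.seed(12)
  d <- c(30L, 30L, 30L)
  ctr_vox <- cbind(sample(5:26, 6, TRUE), sample(5:26, 6, TRUE),
                   sample(5:26, 6, TRUE))
  ctr_um <- cbind(ctr_vox[, 3] - 1, ctr_vox[, 2] - 1, ctr_vox[, 1] - 1)
  mask <- array(1, d)
  dm <- density_map(ctr_um, mask, radius_voxels = 5, voxel_size_um = 1)
  expect_equal(dm$counts, brute_force_density(ctr_vox, d, 5))
  # one centroid: exactly 1 on its ball, 0 elsewhere
  one <- density_map(ctr_um[1, , drop = FALSE], mask, 5, 1)
  expect_true(all(one$counts %in% 0:1))
  expect_equal(sum(one$counts), sum(brute_force_density(ctr_vox[1, , drop = FALSE], d, 5)))
  # k coincident centroids count k
  thrice <- density_map(ctr_um[c(1, 1, 1), ], mask, 5, 1)
  expect_equal(thrice$counts, 3 * one$counts)
  # linearity over a disjoint split
  a <- density_map(ctr_um[1:3, ], mask, 5, 1)
  b <- density_map(ctr_um[4:6, ], mask, 5, 1)
  expect_equal(a$counts + b$counts, dm$counts)
  expect_error(density_map(ctr_um, mask, 40, 1), "exceeds")
  expect_error(density_map(ctr_um, mask, 0, 1), ">= 1")
  # masked voxels report zero
  m2 <- array(0, d); m2[15, 15, 15] <- 1
  dm2 <- density_map(ctr_um, m2, 5, 1)
  expect_equal(sum(dm2$counts != 0), sum(dm$counts[15, 15, 15] != 0))
})

test_that("cohort density multipliers reproduce the low-density shift", {
  base <- phantom_spec(shape = c(48L, 48L, 48L), n_nuclei = 120L, seed = 37L)
  co <- generate_cohort(5L, c(0.85, 0.85, 1, 1, 1), base)
  counts <- vapply(co, function(s) nrow(s$truth$centroids_um), integer(1))
  # direction check: the thinned specimens sit below the untouched ones
  expect_lt(mean(counts[1:2]), mean(counts[3:5]))
  mask <- array(1, c(48L, 48L, 48L))
  dens <- lapply(co, function(s)
    density_map(s$truth$centroids_um, mask, radius_voxels = 10,
                voxel_size_um = base$voxel_size_um)$counts)
  lo <- unlist(lapply(dens[1:2], as.vector))
  hi <- unlist(lapply(dens[3:5], as.vector))
  w <- stats::wilcox.test(lo, hi, alternative = "less")
  expect_lt(w$p.value, 0.01)
})
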