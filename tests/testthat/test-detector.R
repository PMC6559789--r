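toy_features <- function(n = 200, seed = 1) {
  set.seed(seed)
  cls <- rep(c("background", "nucleus"), each = n / 2)
  x <- cbind(f1 = rnorm(n, ifelse(cls == "nucleus", 4, -4)),
             f2 = rnorm(n))
  list(x = x, cls = cls)
}

test_that("the forest separates a separable toy problem and is reproducible", {
  toy <- toy_features()
  m1 <- train_classifier(toy$x, toy$cls, n_trees = 50, seed = 42)
  p1 <- m1$predict_fun(toy$x)
  expect_true(all((p1 > 0.5) == (toy$cls == "nucleus")))
  m2 <- train_classifier(toy$x, toy$cls, n_trees = 50, seed = 42)
  expect_identical(p1, m2$predict_fun(toy$x))
  expect_error(train_classifier(toy$x, rep("nucleus", 200)), "both classes")
})

test_that("swapping the class labels flips the probabilities", {
  toy <- toy_features(seed = 3)
  m <- train_classifier(toy$x, toy$cls, n_trees = 100, seed = 7)
  swapped <- ifelse(toy$cls == "nucleus", "background", "nucleus")
  ms <- train_classifier(toy$x, swapped, n_trees = 100, seed = 7)
  expect_lt(max(abs(m$predict_fun(toy$x) + ms$predict_fun(toy$x) - 1)), 0.1)
})

test_that("classify_plane assembles full-grid probabilities for any axis", {
  vol <- volume3d(array(rnorm(24^3, 100, 5), dim = c(24, 24, 24)), 1)
  dummy <- voxel_classifier(function(f) rep(0.5, nrow(f)),
                            feature_spec(scales = c(1, 2)))
  for (ax in 1:3) {
    pv <- classify_plane(vol, dummy, ax)
    expect_equal(dim(pv$p), c(24, 24, 24))
    expect_true(all(pv$p == 0.5))
  }
  expect_error(classify_plane(vol, dummy, 4), "axis")
  expect_error(classify_plane(vol, dummy, 0), "axis")
})

test_that("orthogonal fusion is a commutative product bounded by its inputs", {
  set.seed(5)
  mk <- function() structure(list(p = array(runif(8^3), dim = c(8, 8, 8)),
                                  plane = "x", voxel_size_um = 1),
                             class = "probability_volume")
  a <- mk(); b <- mk(); c_ <- mk()
  f1 <- combine_probabilities(a, b, c_)
  expect_equal(f1$p, a$p * b$p * c_$p)
  expect_equal(combine_probabilities(c_, a, b)$p, f1$p)
  expect_true(all(f1$p <= pmin(a$p, pmin(b$p, c_$p))))
  expect_equal(combine_probabilities(a, a, a)$p[a$p == 0],
               numeric(sum(a$p == 0)) ) # zeros absorb
  bad <- structure(list(p = array(0.5, dim = c(8, 8, 9)), plane = "x",
                        voxel_size_um = 1), class = "probability_volume")
  expect_error(combine_probabilities(a, b, bad), "shape")
})

test_that("segmentation honours the 8-voxel size filter and splits blobs", {
  p <- array(0, dim = c(20, 20, 20))
  p[2:3, 2:3, 2:3] <- 0.9            # 8 voxels -> kept
  p[10:11, 10:11, 10] <- 0.95        # 4 voxels -> dropped
  p[15:16, 15:16, 15:16] <- 0.85     # 8 voxels -> kept
  det <- segment_nuclei(p, detection_params(), voxel_size_um = 1)
  expect_equal(nrow(det$table), 2L)
  expect_equal(sort(det$table$n_voxels), c(8L, 8L))
  # 7-voxel object is rejected
  p2 <- array(0, dim = c(12, 12, 12))
  p2[2:3, 2:3, 2:3] <- 0.9; p2[3, 3, 3] <- 0
  expect_equal(nrow(segment_nuclei(p2, detection_params(),
                                   voxel_size_um = 1)$table), 0L)
  # raising the threshold never adds voxels
  set.seed(9)
  pr <- array(runif(15^3), dim = c(15, 15, 15))
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    d <- segment_nuclei(pr, detection_params(threshold = th, min_voxels = 1),
                        voxel_size_um = 1)
    sum(d$table$n_voxels)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("connectivity 26 merges diagonal touches that connectivity 6 keeps apart", {
  p <- array(0, dim = c(10, 10, 10))
  p[2:3, 2:3, 2:3] <- 1
  p[4, 4, 4] <- 1                     # corner-touches the cube
  d26 <- segment_nuclei(p, detection_params(min_voxels = 1), voxel_size_um = 1)
  d6 <- segment_nuclei(p, detection_params(min_voxels = 1, connectivity = 6),
                       voxel_size_um = 1)
  expect_equal(nrow(d26$table), 1L)
  expect_equal(nrow(d6$table), 2L)
})

test_that("matching reproduces the confusion counts and the F1 formula", {
  pts <- matrix(runif(30, 0, 50), 10, 3)
  m <- match_detections(pts, pts, 3)
  expect_equal(c(m$TP, m$FP, m$FN), c(10L, 0L, 0L))
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  # 9 matched, 1 spurious, 1 missed
  truth <- rbind(pts, c(100, 100, 100))
  det <- rbind(pts[1:9, ], c(200, 200, 200), c(300, 300, 300))
  m2 <- match_detections(det, truth, 3)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(9L, 2L, 2L))
  m3 <- match_detections(rbind(pts[1:9, ], c(200, 200, 200)), pts, 3)
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0.9, 0.9, 0.9))
  expect_error(match_detections(pts, pts, -1), "positive")
  # TP is symmetric in the two point sets
  set.seed(11)
  a <- matrix(runif(60, 0, 40), 20, 3)
  b <- matrix(runif(45, 0, 40), 15, 3)
  expect_equal(match_detections(a, b, 5)$TP, match_detections(b, a, 5)$TP)
})

test_that("greedy matching attains the optimal assignment on small instances", {
  perm_oracle <- function(det, tru, r) {
    n <- nrow(det); best <- 0L
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    D <- as.matrix(dist(rbind(det, tru)))[seq_len(n), n + seq_len(nrow(tru))]
    for (p in perms(seq_len(nrow(tru)))) {
      tp <- sum(D[cbind(seq_len(min(n, nrow(tru))),
                        p[seq_len(min(n, nrow(tru)))])] <= r)
      best <- max(best, tp)
    }
    best
  }
  set.seed(13)
  for (i in 1:10) {
    det <- matrix(runif(18, 0, 20), 6, 3)
    tru <- det + matrix(rnorm(18, 0, 1.0), 6, 3)
    expect_equal(match_detections(det, tru, 2.5)$TP, perm_oracle(det, tru, 2.5))
  }
})

test_that("threshold calibration reports a self-consistent F1 curve", {
  p <- array(0, dim = c(16, 16, 16))
  p[2:3, 2:3, 2:3] <- 1; p[8:9, 8:9, 8:9] <- 1
  truth <- rbind(c(1.5, 1.5, 1.5), c(7.5, 7.5, 7.5))
  res <- optimize_threshold(p, truth, thresholds = seq(0.2, 0.8, 0.2),
                            params = detection_params(min_voxels = 4),
                            voxel_size_um = 1, match_radius_um = 3)
  expect_equal(nrow(res$curve), 4L)
  expect_equal(res$best_f1, max(res$curve$f1))
  # probabilities in {0,1}: F1 flat over interior thresholds
  expect_true(all(res$curve$f1 == res$curve$f1[1]))
  expect_equal(res$best_threshold, 0.2)   # smallest-threshold tie-break
  expect_error(optimize_threshold(p, truth[0, , drop = FALSE]),
               "empty reference")
})

test_that("the fused pipeline recovers phantom nuclei", {
  ph <- tiny_phantom()
  lb <- sparse_labels_from_truth(ph$truth, box_edge = 30L, bg_per_box = 1500L)
  res <- detect_nuclei(ph$volume, lb, n_trees = 50L)
  expect_true(all(res$p_total$p <= pmin(res$p_plane[[1]]$p,
                                        pmin(res$p_plane[[2]]$p,
                                             res$p_plane[[3]]$p)) + 1e-12))
  m <- match_detections(res$nuclei, ph$truth$centroids_um)
  expect_gte(m$f1, 0.9)
})
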