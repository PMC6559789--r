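#' Sparse voxel training labels
#'
#' Voxel coordinates annotated as nucleus or background, typically confined
#' to a few cubic training regions (the default workflow annotates three
#' 75-voxel cubes spread over the brain and notochord).
#'
#' @param coords integer matrix of voxel indices (columns z, y, x, 1-based).
#' @param class character vector, `"nucleus"` or `"background"`, per row.
#' @param boxes optional list of training boxes, each a 2x3 matrix of
#'   (min, max) voxel bounds.
#' @return object of class `sparse_labels`.
#' @export
sparse_labels <- function(coords, class, boxes = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(class)) stop("one class per coordinate required")
  if (!all(class %in% c("nucleus", "background")))
    stop("classes must be 'nucleus' or 'background'")
  structure(list(coords = coords, class = as.character(class), boxes = boxes),
            class = "sparse_labels")
}

#' Derive sparse training labels from phantom ground truth
#'
#' Emulates manual annotation: inside each training box, every ground-truth
#' nucleus voxel is a positive example and a random sample of the remaining
#' voxels are background examples.
#'
#' @param truth a `ground_truth` from [generate_nuclei_phantom()].
#' @param boxes list of 2x3 matrices (min and max z,y,x voxel bounds); the
#'   default places three cubes of `box_edge` voxels across the volume.
#' @param box_edge edge length (voxels) of the default training cubes.
#' @param bg_per_box number of background voxels sampled per box.
#' @param seed RNG seed for the background sample.
#' @return a [sparse_labels()].
#' @export
sparse_labels_from_truth <- function(truth, boxes = NULL, box_edge = 75L,
                                     bg_per_box = 4000L, seed = 1L) {
  d <- truth$shape
  if (is.null(boxes)) {
    e <- pmin(box_edge, d - 2L)
    anchor <- function(fz, fy, fx) {
      lo <- pmax(1L, c(round(fz * (d[1] - e[1])), round(fy * (d[2] - e[2])),
                       round(fx * (d[3] - e[3]))) + 1L)
      rbind(lo, lo + e - 1L)
    }
    boxes <- list(anchor(0.1, 0.1, 0.1), anchor(0.5, 0.5, 0.5),
                  anchor(0.8, 0.2, 0.7))
  }
  nuc <- do.call(rbind, truth$voxels)
  if (is.null(nuc)) nuc <- matrix(integer(), 0, 3)
  with_seed(seed, {
    coords <- list(); cls <- list()
    for (b in boxes) {
      inb <- nuc[, 1] >= b[1, 1] & nuc[, 1] <= b[2, 1] &
             nuc[, 2] >= b[1, 2] & nuc[, 2] <= b[2, 2] &
             nuc[, 3] >= b[1, 3] & nuc[, 3] <= b[2, 3]
      pos <- nuc[inb, , drop = FALSE]
      ng <- as.matrix(expand.grid(z = b[1, 1]:b[2, 1], y = b[1, 2]:b[2, 2],
                                  x = b[1, 3]:b[2, 3]))
      lin_pos <- (pos[, 3] - 1) * d[1] * d[2] + (pos[, 2] - 1) * d[1] + pos[, 1]
      lin_all <- (ng[, 3] - 1) * d[1] * d[2] + (ng[, 2] - 1) * d[1] + ng[, 1]
      bg <- ng[!(lin_all %in% lin_pos), , drop = FALSE]
      bg <- bg[sample.int(nrow(bg), min(bg_per_box, nrow(bg))), , drop = FALSE]
      coords <- c(coords, list(pos, bg))
      cls <- c(cls, list(rep("nucleus", nrow(pos)), rep("background", nrow(bg))))
    }
    sparse_labels(do.call(rbind, coords), unlist(cls), boxes = boxes)
  })
}

#' Probabilistic voxel classifier
#'
#' Thin wrapper pairing a prediction function with the feature specification
#' it expects; [train_classifier()] builds one backed by a random forest,
#' but any function mapping a feature matrix to nucleus probabilities (e.g.
#' a constant dummy for testing) can be wrapped.
#'
#' @param predict_fun function(feature matrix) -> probability vector.
#' @param spec the [feature_spec()] the classifier expects.
#' @return object of class `voxel_classifier`.
#' @export
voxel_classifier <- function(predict_fun, spec = feature_spec()) {
  stopifnot(is.function(predict_fun), inherits(spec, "feature_spec"))
  structure(list(predict_fun = predict_fun, spec = spec),
            class = "voxel_classifier")
}

#' Train a random-forest voxel classifier
#'
#' Fits a probability random forest that assigns each voxel a probability of
#' being a nucleus. With a [volume3d()] input and [sparse_labels()], 2D
#' features are computed on the slices (perpendicular to `axis`) containing
#' labelled voxels, matching the per-orthogonal-plane annotation workflow;
#' with a plain feature matrix and a class vector, the forest is fitted
#' directly (useful for toy problems). Class weights balance the two classes.
#'
#' @param x a [volume3d()] or a numeric feature matrix.
#' @param labels a [sparse_labels()] (volume input) or a character vector of
#'   `"nucleus"`/`"background"` (matrix input); both classes must be present.
#' @param axis slicing axis (1 = z, 2 = y, 3 = x) for volume input.
#' @param spec a [feature_spec()].
#' @param n_trees number of trees.
#' @param seed RNG seed; fixed seed gives a reproducible model.
#' @param num_threads threads used by the forest (default 1, deterministic).
#' @return a [voxel_classifier()].
#' @export
train_classifier <- function(x, labels, axis = 1L, spec = feature_spec(),
                             n_trees = 100L, seed = 1L, num_threads = 1L) {
  if (inherits(x, "volume3d")) {
    stopifnot(inherits(labels, "sparse_labels"))
    feats <- matrix(numeric(), 0, 0)
    cls <- labels$class
    rows <- vector("list", 0)
    for (s in sort(unique(labels$coords[, axis]))) {
      sel <- labels$coords[, axis] == s
      f_sl <- compute_features(extract_slice(x$data, axis, s), spec)
      lin <- slice_linear_index(labels$coords[sel, , drop = FALSE], dim(x$data), axis)
      rows[[length(rows) + 1L]] <- f_sl[lin, , drop = FALSE]
    }
    ord <- order(labels$coords[, axis], method = "radix")
    feats <- do.call(rbind, rows)
    cls <- cls[ord]
  } else {
    feats <- as.matrix(x)
    cls <- as.character(labels)
  }
  if (length(unique(cls)) < 2L)
    stop("training labels must contain both classes")
  df <- as.data.frame(feats)
  df$.class <- factor(cls, levels = c("background", "nucleus"))
  wt <- 1 / table(df$.class)[df$.class]
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = n_trees, probability = TRUE,
                        case.weights = as.numeric(wt),
                        seed = seed, num.threads = num_threads)
  cn <- colnames(df)[colnames(df) != ".class"]
  voxel_classifier(function(f) {
    f <- as.data.frame(f)
    colnames(f) <- cn
    predict(fit, data = f, num.threads = num_threads)$predictions[, "nucleus"]
  }, spec)
}

extract_slice <- function(arr, axis, i) {
  switch(axis, arr[i, , , drop = TRUE], arr[, i, , drop = TRUE],
         arr[, , i, drop = TRUE])
}

# linear indices of (z,y,x) coords within the 2D slice at their `axis` value
slice_linear_index <- function(coords, d, axis) {
  if (axis == 1L) (coords[, 3] - 1) * d[2] + coords[, 2]
  else if (axis == 2L) (coords[, 3] - 1) * d[1] + coords[, 1]
  else (coords[, 2] - 1) * d[1] + coords[, 1]
}

#' Per-voxel nucleus probabilities from slices along one axis
#'
#' Classifies every slice perpendicular to `axis` (1 = z giving transverse,
#' 2 = y coronal, 3 = x sagittal slices) and assembles a full-grid
#' probability volume.
#'
#' @param volume a [volume3d()].
#' @param model a [voxel_classifier()].
#' @param axis 1, 2 or 3.
#' @param block number of slices whose features are batched per prediction.
#' @return object of class `probability_volume`: list with `p` (3D array in
#'   `[0,1]`), `plane` and `voxel_size_um`.
#' @export
classify_plane <- function(volume, model, axis, block = 16L) {
  stopifnot(inherits(volume, "volume3d"), inherits(model, "voxel_classifier"))
  if (!(length(axis) == 1L && axis %in% 1:3))
    stop("`axis` must be 1, 2 or 3")
  d <- dim(volume$data)
  p <- array(NA_real_, dim = d)
  slices <- seq_len(d[axis])
  for (s0 in seq(1L, d[axis], by = block)) {
    ss <- slices[s0:min(d[axis], s0 + block - 1L)]
    feats <- do.call(rbind, lapply(ss, function(s)
      compute_features(extract_slice(volume$data, axis, s), model$spec)))
    pr <- model$predict_fun(feats)
    per <- length(pr) / length(ss)
    for (j in seq_along(ss)) {
      vals <- pr[((j - 1) * per + 1):(j * per)]
      if (axis == 1L) p[ss[j], , ] <- vals
      else if (axis == 2L) p[, ss[j], ] <- vals
      else p[, , ss[j]] <- vals
    }
  }
  structure(list(p = p, plane = c("transverse", "coronal", "sagittal")[axis],
                 voxel_size_um = volume$voxel_size_um),
            class = "probability_volume")
}

#' Fuse orthogonal-plane probabilities by voxelwise product
#'
#' `P_total(x,y,z) = P_coronal * P_sagittal * P_transverse`: a voxel is kept
#' only if all three per-plane classifiers agree, so the fused probability
#' never exceeds the smallest input.
#'
#' @param p_cor,p_sag,p_tra `probability_volume`s on identical grids (any
#'   order; the product is commutative).
#' @return a combined `probability_volume`.
#' @export
combine_probabilities <- function(p_cor, p_sag, p_tra) {
  pp <- list(p_cor, p_sag, p_tra)
  stopifnot(all(vapply(pp, inherits, logical(1), "probability_volume")))
  d <- dim(pp[[1]]$p)
  if (!all(vapply(pp, function(q) identical(dim(q$p), d), logical(1))))
    stop("probability volumes differ in shape")
  structure(list(p = pp[[1]]$p * pp[[2]]$p * pp[[3]]$p, plane = "combined",
                 voxel_size_um = pp[[1]]$voxel_size_um),
            class = "probability_volume")
}
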